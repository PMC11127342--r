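#' Write variants as VCF 4.2
#'
#' Positions are 1-based; INDELs carry the preceding anchor base in both
#' alleles, as produced by [extract_variants()]. One haploid genotype
#' column is written per sample: `1` where the sample carries the variant,
#' `0` otherwise.
#'
#' @param variants An [mga_variants()] tibble, or a list of them (one per
#'   sample, merged into a multi-sample VCF on matching records).
#' @param reference The reference [mga_genome()]; every REF allele is
#'   checked against it.
#' @param path Output path.
#' @param sample_ids Sample column names; defaults to the sample labels in
#'   `variants`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, reference, path, sample_ids = NULL) {
  if (inherits(variants, "mga_variants")) variants <- list(variants)
  all_v <- bind_rows(lapply(variants, as_tibble))
  if (is.null(sample_ids)) sample_ids <- unique(all_v$sample)
  if (!nrow(all_v)) {
    keys <- tibble(chrom = character(), pos = integer(), ref = character(), alt = character())
  } else {
    keys <- distinct(all_v[c("chrom", "pos", "ref", "alt")])
    keys <- arrange(keys, .data$chrom, .data$pos, .data$ref, .data$alt)
    obs <- substr(keys$ref, 1L, 1L)
    for (i in seq_len(nrow(keys))) {
      have <- seq_slice(reference, keys$chrom[i], keys$pos[i] - 1L,
                        keys$pos[i] - 1L + nchar(keys$ref[i]))
      if (have != keys$ref[i])
        abort(sprintf("REF allele %s disagrees with reference at %s:%d (genome has %s)",
                      keys$ref[i], keys$chrom[i], keys$pos[i], have))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=minimga",
               sprintf("##contig=<ID=%s,length=%d>", names(reference$seq), nchar(reference$seq)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                     "FORMAT", sample_ids), collapse = "\t"), con)
  if (nrow(keys)) {
    gt <- matrix("0", nrow(keys), length(sample_ids),
                 dimnames = list(NULL, sample_ids))
    kk <- paste(keys$chrom, keys$pos, keys$ref, keys$alt)
    for (vs in variants) {
      d <- as_tibble(vs)
      if (!nrow(d)) next
      hit <- match(paste(d$chrom, d$pos, d$ref, d$alt), kk)
      gt[cbind(hit, match(d$sample, sample_ids))] <- "1"
    }
    writeLines(paste(keys$chrom, keys$pos, ".", keys$ref, keys$alt, ".", ".", ".",
                     "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF written by [write_vcf()] back into per-sample variant sets
#'
#' Minimal reader for the haploid, biallelic records this package emits.
#'
#' @param path Path to a VCF file.
#' @param reference_id Reference genome label to attach.
#' @return Named list of [mga_variants()] tibbles, one per sample column.
#' @export
read_vcf <- function(path, reference_id = "reference") {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) abort("missing #CHROM header line")
  cols <- str_split(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  f <- str_split(body, "\t")
  out <- lapply(samples, function(s) {
    idx <- 9L + match(s, samples)
    keep <- map_chr(f, function(x) x[idx]) == "1"
    d <- tibble(chrom = map_chr(f, 1)[keep],
                pos = as.integer(map_chr(f, 2)[keep]),
                ref = map_chr(f, 4)[keep],
                alt = map_chr(f, 5)[keep])
    mga_variants(d, sample = s, reference_id = reference_id)
  })
  setNames(out, samples)
}
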