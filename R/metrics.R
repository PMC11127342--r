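#' Position-match and aligned-base metrics per region class
#'
#' For each reference position inside the region set, coverage is the
#' number of alignment columns at that position where both rows are
#' non-gap. `position_match_bp` counts positions with coverage at least 1
#' (a position match is an ungapped alignment column, matched or
#' mismatched); `aligned_bp` sums coverage over positions, counting
#' multiplicity (a depth sum).
#'
#' @param blocks List of two-row + strand pairwise [mga_block()]s,
#'   reference row first.
#' @param regions An [region_set()] or a (possibly named) list of them.
#' @param ref The reference [mga_genome()].
#' @return Tibble with one row per region class: `region`, `region_bp`,
#'   `position_match_bp`, `aligned_bp`.
#' @export
region_metrics <- function(blocks, regions, ref) {
  if (inherits(regions, "mga_regions")) regions <- list(regions)
  cov <- lapply(genome_lengths(ref), function(L) integer(L))
  for (b in blocks) {
    if (nrow(b$rows) != 2) abort("region_metrics expects pairwise blocks")
    chrom <- b$rows$seq[1]
    if (is.null(cov[[chrom]])) abort(paste0("block on unknown reference sequence ", chrom))
    cr <- column_positions(b$text[1], b$rows$start[1])
    cq <- column_positions(b$text[2], b$rows$start[2])
    covered <- cr$pos[cr$nongap & cq$nongap] + 1L
    if (length(covered))
      cov[[chrom]] <- cov[[chrom]] + tabulate(covered, nbins = length(cov[[chrom]]))
  }
  rows <- lapply(regions, function(rg) {
    miss <- setdiff(unique(rg$seq), names(cov))
    if (length(miss))
      abort(paste0("region sequences absent from the reference: ", paste(miss, collapse = ", ")))
    pm <- 0L; ab <- 0
    for (i in seq_len(nrow(rg))) {
      cv <- cov[[rg$seq[i]]][(rg$start[i] + 1L):rg$end[i]]
      pm <- pm + sum(cv >= 1L)
      ab <- ab + sum(cv)
    }
    tibble(region = attr(rg, "label"), region_bp = region_length(rg),
           position_match_bp = pm, aligned_bp = ab)
  })
  bind_rows(rows)
}

# 1-based reference footprint of each variant record: a deletion covers its
# deleted interval, an SNV its single position, an insertion its anchor base
variant_footprints <- function(d) {
  len <- abs(nchar(d$ref) - nchar(d$alt))
  end_anchored <- d$vclass != "SNV" &
    substr(d$ref, 1, 1) != substr(d$alt, 1, 1)
  start <- ifelse(d$vclass == "DEL", ifelse(end_anchored, d$pos, d$pos + 1L), d$pos)
  end <- ifelse(d$vclass == "DEL", start + len - 1L, start)
  tibble(chrom = d$chrom, start = as.integer(start), end = as.integer(end),
         vclass = d$vclass,
         allele = paste(d$chrom, d$pos, d$ref, d$alt, sep = ":"))
}

#' INDEL length spectrum and mod-3 coding enrichment
#'
#' Bins INDEL lengths and contrasts, inside versus outside the CDS region
#' set, the fraction of INDELs whose length is a multiple of three —
#' the selection signature expected in coding sequence, where frame-
#' preserving events are tolerated. An INDEL is "in CDS" when its
#' reference footprint (the deleted interval for deletions, the anchor
#' base for insertions) intersects the CDS set. The CDS fraction is tested
#' against the non-CDS fraction with a two-sided binomial test.
#'
#' @param variants A normalized [mga_variants()] tibble (or list of them,
#'   pooled).
#' @param cds An [region_set()] of CDS intervals on the reference.
#' @return List of class `mga_indel_spectrum`: `spectrum` (tibble of
#'   per-length-bin counts by region), `cds_mod3_fraction`,
#'   `noncds_mod3_fraction`, `ratio` (`NA` when a class is empty),
#'   `p_value`, `n_cds`, `n_noncds`.
#' @export
indel_spectrum <- function(variants, cds) {
  if (inherits(variants, "mga_variants")) variants <- list(variants)
  d <- bind_rows(lapply(variants, as_tibble))
  d <- d[d$vclass %in% c("INS", "DEL"), ]
  if (!nrow(d)) {
    return(structure(list(
      spectrum = tibble(bin = character(), region = character(), n = integer()),
      cds_mod3_fraction = NA_real_, noncds_mod3_fraction = NA_real_,
      ratio = NA_real_, p_value = NA_real_, n_cds = 0L, n_noncds = 0L),
      class = "mga_indel_spectrum"))
  }
  fp <- variant_footprints(d)
  in_cds <- rep(FALSE, nrow(d))
  for (chrom in unique(fp$chrom)) {
    ir <- regions_ir(cds, chrom)
    sel <- which(fp$chrom == chrom)
    if (!length(ir)) next
    q <- IRanges::IRanges(start = fp$start[sel], end = fp$end[sel])
    in_cds[sel] <- IRanges::overlapsAny(q, ir)
  }
  len <- abs(nchar(d$ref) - nchar(d$alt))
  bin <- ifelse(len > 50, ">50", as.character(len))
  spectrum <- summarise(group_by(tibble(bin = bin,
                                        region = ifelse(in_cds, "CDS", "non-CDS")),
                                 .data$bin, .data$region),
                        n = n(), .groups = "drop")
  n_cds <- sum(in_cds); n_non <- sum(!in_cds)
  f_cds <- if (n_cds) sum(len[in_cds] %% 3 == 0) / n_cds else NA_real_
  f_non <- if (n_non) sum(len[!in_cds] %% 3 == 0) / n_non else NA_real_
  ratio <- if (!is.na(f_cds) && !is.na(f_non) && f_non > 0) f_cds / f_non else NA_real_
  p <- if (n_cds > 0 && n_non > 0 && !is.na(f_non) && f_non > 0 && f_non < 1) {
    binom.test(sum(len[in_cds] %% 3 == 0), n_cds, p = f_non)$p.value
  } else NA_real_
  structure(list(spectrum = spectrum, cds_mod3_fraction = f_cds,
                 noncds_mod3_fraction = f_non, ratio = ratio, p_value = p,
                 n_cds = n_cds, n_noncds = n_non),
            class = "mga_indel_spectrum")
}

#' @export
print.mga_indel_spectrum <- function(x, ...) {
  cat(sprintf("<indel spectrum> %d CDS / %d non-CDS INDELs; mod-3 fraction %.3f vs %.3f (ratio %.2f, p = %.3g)\n",
              x$n_cds, x$n_noncds, x$cds_mod3_fraction, x$noncds_mod3_fraction,
              x$ratio, x$p_value))
  invisible(x)
}

#' Reference base pairs affected by multi-allelic variants
#'
#' A locus is multi-allelic when the reference footprints of two or more
#' distinct alleles (different `(chrom, pos, ref, alt)`, possibly from
#' different samples) intersect. Deletions participating in any
#' multi-allelic locus contribute their whole deleted interval; a
#' multi-allelic locus whose participants are all SNVs or insertions
#' contributes one base pair. `affected_bp` is the size of the union of
#' those contributions (the default), or their sum with
#' `overlap = "sum"`.
#'
#' @param sets List of normalized [mga_variants()] sets against the same
#'   reference.
#' @param ref The reference [mga_genome()].
#' @param overlap How overlapping deletion footprints are combined:
#'   `"union"` (default; a genome fraction stays below 1) or `"sum"`
#'   (cumulative lengths).
#' @return List of class `mga_multiallelic`: `affected_bp`, `genome_bp`,
#'   `fraction`.
#' @export
count_multiallelic <- function(sets, ref, overlap = c("union", "sum")) {
  overlap <- match.arg(overlap)
  refs <- unique(map_chr(sets, ~ attr(.x, "reference_id")))
  if (length(refs) > 1)
    abort(paste0("variant sets use different references: ", paste(refs, collapse = ", ")))
  d <- distinct(bind_rows(lapply(sets, function(x) as_tibble(x)[c("chrom", "pos", "ref", "alt", "vclass")])))
  genome_bp <- sum(genome_lengths(ref))
  affected <- 0
  if (nrow(d)) {
    fp <- variant_footprints(d)
    for (chrom in unique(fp$chrom)) {
      f <- fp[fp$chrom == chrom, ]
      ir <- IRanges::IRanges(start = f$start, end = f$end)
      # a variant participates when its footprint meets a distinct allele's
      participates <- IRanges::countOverlaps(ir, ir) >= 2L
      if (!any(participates)) next
      dels <- participates & f$vclass == "DEL"
      del_ir <- ir[dels]
      # point loci whose participants are all SNV/INS: one bp each
      pts <- f[participates & f$vclass != "DEL", ]
      pt_pos <- unique(pts$start[duplicated(pts$start)])
      pt_ir <- IRanges::IRanges(start = pt_pos, width = 1L)
      if (overlap == "union") {
        affected <- affected +
          sum(IRanges::width(IRanges::reduce(c(del_ir, pt_ir))))
      } else {
        pt_only <- pt_ir[!IRanges::overlapsAny(pt_ir, del_ir)]
        affected <- affected + sum(IRanges::width(del_ir)) + length(pt_only)
      }
    }
  }
  structure(list(affected_bp = as.integer(affected), genome_bp = genome_bp,
                 fraction = affected / genome_bp),
            class = "mga_multiallelic")
}

#' @export
print.mga_multiallelic <- function(x, ...) {
  cat(sprintf("<multi-allelic> %s bp affected of %s (%.2f%%)\n",
              format(x$affected_bp, big.mark = ","),
              format(x$genome_bp, big.mark = ","), 100 * x$fraction))
  invisible(x)
}
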