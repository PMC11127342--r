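#' Feature table (gene / mRNA / CDS annotation)
#'
#' A tibble of gene-model features with internal 0-based half-open
#' coordinates (conversion to and from the 1-based inclusive GFF convention
#' happens only in [read_gff()] / [write_gff()]). Columns: `seq`, `start`,
#' `end`, `strand`, `type` (one of gene/mRNA/CDS), `feature_id`,
#' `parent_id`.
#'
#' @param df Data frame with the columns above.
#' @param genome Optional [mga_genome()] to bound-check intervals against.
#' @return A tibble of class `mga_features`.
#' @export
mga_features <- function(df, genome = NULL) {
  df <- as_tibble(df)
  need <- c("seq", "start", "end", "strand", "type", "feature_id", "parent_id")
  if (!all(need %in% names(df)))
    abort(paste0("missing feature columns: ", paste(setdiff(need, names(df)), collapse = ", ")))
  df <- df[need]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (nrow(df)) {
    if (any(df$start >= df$end))
      abort(paste0("feature with start >= end: ",
                   paste(df$feature_id[df$start >= df$end], collapse = ", ")))
    if (!all(df$type %in% c("gene", "mRNA", "CDS")))
      abort("feature types must be gene, mRNA or CDS")
    if (!all(df$strand %in% c("+", "-")))
      abort("feature strand must be + or -")
    cds <- df[df$type == "CDS", ]
    known <- df$feature_id[df$type %in% c("gene", "mRNA")]
    orphan <- cds$feature_id[!(cds$parent_id %in% known)]
    if (length(orphan))
      abort(paste0("CDS without resolvable parent: ", paste(unique(orphan), collapse = ", ")))
    if (!is.null(genome)) {
      len <- genome_lengths(genome)
      miss <- setdiff(unique(df$seq), names(len))
      if (length(miss))
        abort(paste0("features on sequences absent from the genome: ",
                     paste(miss, collapse = ", ")))
      oob <- df$end > len[df$seq]
      if (any(oob))
        abort(paste0("feature(s) out of sequence bounds: ",
                     paste(df$feature_id[oob], collapse = ", ")))
    }
  }
  df <- arrange(df, .data$seq, .data$start, .data$end)
  class(df) <- c("mga_features", class(df))
  df
}

#' Read gene annotation from a GFF3 file
#'
#' Only `gene`, `mRNA` and `CDS` features are retained; parent links are
#' resolved from the `Parent` attribute. GFF coordinates (1-based
#' inclusive) are converted to the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param genome The [mga_genome()] the annotation describes; features on
#'   sequences absent from it are rejected.
#' @return An [mga_features()] tibble.
#' @export
read_gff <- function(path, genome) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "mRNA", "CDS")
  gr <- gr[keep]
  ids <- as.character(gr$ID)
  par <- vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
                character(1))
  type <- as.character(gr$type)
  miss_id <- is.na(ids) | ids == ""
  ids[miss_id] <- paste0(tolower(type[miss_id]), "-", seq_len(sum(miss_id)))
  df <- tibble(
    seq = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type, feature_id = ids, parent_id = par)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  mga_features(df, genome = genome)
}

#' Write a feature table as GFF3
#' @param features An [mga_features()] tibble.
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff <- function(features, path, source = "minimga") {
  stopifnot(inherits(features, "mga_features"))
  gr <- GenomicRanges::GRanges(
    seqnames = features$seq,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  gr$source <- source
  gr$type <- features$type
  gr$phase <- ifelse(features$type == "CDS", 0L, NA_integer_)
  gr$ID <- features$feature_id
  gr$Parent <- ifelse(is.na(features$parent_id), NA_character_, features$parent_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
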