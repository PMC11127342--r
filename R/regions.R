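#' Region set (merged genomic intervals of one class)
#'
#' A labelled set of 0-based half-open intervals, sorted and merged per
#' sequence on construction. Region classes are typically CDS, genic,
#' repeat, or whole-genome.
#'
#' @param df Data frame with columns `seq`, `start`, `end` (0-based
#'   half-open).
#' @param label Region-class label.
#' @return A tibble of class `mga_regions` with attribute `label`.
#' @export
region_set <- function(df, label = "region") {
  df <- as_tibble(df)[c("seq", "start", "end")]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (nrow(df) && any(df$end <= df$start))
    abort("region with end <= start")
  if (nrow(df)) {
    merged <- lapply(split(df, df$seq), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
      tibble(seq = d$seq[[1]], start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    })
    df <- arrange(bind_rows(merged), .data$seq, .data$start)
  }
  attr(df, "label") <- label
  class(df) <- c("mga_regions", class(df))
  df
}

#' Total length of a region set
#' @param regions An [region_set()].
#' @return Total interval length in bp.
#' @export
region_length <- function(regions) {
  stopifnot(inherits(regions, "mga_regions"))
  if (!nrow(regions)) return(0L)
  sum(regions$end - regions$start)
}

#' Read a BED file into a region set
#'
#' Accepts 3+ column BED (0-based half-open); intervals are sorted and
#' merged. Lines with `end <= start` are rejected with their line number.
#'
#' @param path Path to a BED file.
#' @param label Region-class label; defaults to the file name.
#' @return An [region_set()].
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(label)) label <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(region_set(tibble(seq = character(), start = integer(), end = integer()), label))
  parts <- str_split(trimws(lines), "\\s+")
  if (any(lengths(parts) < 3))
    abort(paste0("BED line with fewer than 3 fields at line ",
                 which(lengths(parts) < 3)[1]))
  seqn <- map_chr(parts, 1)
  start <- suppressWarnings(as.integer(map_chr(parts, 2)))
  end <- suppressWarnings(as.integer(map_chr(parts, 3)))
  if (anyNA(start) || anyNA(end))
    abort(paste0("non-numeric BED coordinates at line ", which(is.na(start) | is.na(end))[1]))
  bad <- end <= start
  if (any(bad))
    abort(paste0("BED interval with end <= start at line ", which(bad)[1]))
  region_set(tibble(seq = seqn, start = start, end = end), label)
}

#' Write a region set as 3-column BED
#' @param regions An [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "mga_regions"))
  if (nrow(regions)) {
    write.table(regions[c("seq", "start", "end")], path, quote = FALSE,
                sep = "\t", row.names = FALSE, col.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Whole-genome region set for a genome
#' @param genome An [mga_genome()].
#' @param label Region-class label.
#' @return An [region_set()] covering every sequence end to end.
#' @export
whole_genome_regions <- function(genome, label = "whole-genome") {
  len <- genome_lengths(genome)
  region_set(tibble(seq = names(len), start = 0L, end = unname(len)), label)
}

# intersect a sorted position vector (1-based) with a region set on one seq
regions_ir <- function(regions, seq_name) {
  d <- regions[regions$seq == seq_name, ]
  IRanges::IRanges(start = d$start + 1L, end = d$end)
}
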