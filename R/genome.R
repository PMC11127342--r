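#' Genome container
#'
#' A genome is a set of named uppercase nucleotide sequences (`A`, `C`, `G`,
#' `T`, `N`) plus the fraction of input letters that were soft-masked
#' (lowercase). Masking is recorded but never used to suppress anchors:
#' anchoring on genes does not depend on repeat masking, and suppressing
#' masked seeds would prevent alignment from initiating in repeat regions.
#'
#' @param genome_id Single string naming the genome.
#' @param sequences Named character vector of nucleotide strings.
#' @param masked_fraction Fraction of input letters that were lowercase.
#' @return An object of class `mga_genome`: a list with elements
#'   `genome_id`, `seq` (named character vector) and `masked_fraction`.
#' @examples
#' g <- mga_genome("toy", c(chr1 = "ACGTACGT"))
#' genome_lengths(g)
#' @export
mga_genome <- function(genome_id, sequences, masked_fraction = 0) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  sequences <- toupper(unlist(sequences))
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == ""))
    abort("all sequences must be named")
  if (anyDuplicated(names(sequences)))
    abort(paste0("duplicate sequence names: ",
                 paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", ")))
  if (any(nchar(sequences) < 1L))
    abort(paste0("zero-length sequence: ",
                 paste(names(sequences)[nchar(sequences) < 1L], collapse = ", ")))
  bad <- str_detect(sequences, "[^ACGTN]")
  if (any(bad))
    abort(paste0("non-nucleotide characters in: ", paste(names(sequences)[bad], collapse = ", ")))
  structure(list(genome_id = genome_id, seq = sequences,
                 masked_fraction = masked_fraction),
            class = "mga_genome")
}

#' @export
print.mga_genome <- function(x, ...) {
  cat(sprintf("<mga_genome> %s: %d sequence(s), %s bp total, %.1f%% soft-masked on input\n",
              x$genome_id, length(x$seq), format(sum(nchar(x$seq)), big.mark = ","),
              100 * x$masked_fraction))
  invisible(x)
}

#' Sequence lengths of a genome
#' @param genome An [mga_genome()].
#' @return Named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  stopifnot(inherits(genome, "mga_genome"))
  setNames(nchar(genome$seq), names(genome$seq))
}

#' Read a FASTA file into a genome
#'
#' Sequences are uppercased; the lowercase (soft-masked) fraction is
#' recorded. IUPAC ambiguity codes other than `N` are converted to `N` with
#' a warning giving the conversion count.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Genome label; defaults to the file name without extension.
#' @return An [mga_genome()].
#' @export
read_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) abort(paste0("empty FASTA file: ", path))
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    abort(paste0("duplicate FASTA record name(s) in ", path, ": ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  seqs <- as.character(ss)
  names(seqs) <- nm
  n_total <- sum(nchar(seqs))
  if (any(nchar(seqs) == 0L))
    abort(paste0("empty FASTA record(s): ", paste(nm[nchar(seqs) == 0L], collapse = ", ")))
  n_lower <- sum(str_count(seqs, "[a-z]"))
  seqs <- toupper(seqs)
  n_amb <- sum(str_count(seqs, "[RYSWKMBDHV]"))
  if (n_amb > 0) {
    warn(sprintf("%d IUPAC ambiguity code(s) converted to N", n_amb))
    seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  }
  bad <- str_detect(seqs, "[^ACGTN]")
  if (any(bad))
    abort(paste0("non-nucleotide alphabet in record(s): ", paste(nm[bad], collapse = ", ")))
  mga_genome(genome_id, seqs, masked_fraction = n_lower / n_total)
}

#' Write a genome to FASTA
#' @param genome An [mga_genome()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  stopifnot(inherits(genome, "mga_genome"))
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#' @param x Character vector of `ACGTN` strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open substring of a genome sequence
seq_slice <- function(genome, seq_name, start, end) {
  s <- genome$seq[[seq_name]]
  if (is.null(s)) abort(paste0("no sequence named ", seq_name, " in genome ", genome$genome_id))
  if (start < 0 || end > nchar(s) || start > end)
    abort(sprintf("slice [%d,%d) out of bounds for %s (length %d)", start, end, seq_name, nchar(s)))
  substr(s, start + 1L, end)
}
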