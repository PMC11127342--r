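#' Alignment parameters
#'
#' Scoring and control parameters shared by the pairwise aligner and the
#' progressive pipeline. The gap model is two-piece affine: a gap run of
#' length `L` costs `min(O1 + E1*L, O2 + E2*L)`. The second regime must
#' have the higher open and lower extend cost (`O2 > O1`, `E2 < E1`) so
#' that long gaps are charged near-linearly — the property that lets the
#' aligner keep a long INDEL as one event instead of fragmenting it.
#'
#' Defaults: `match = 2`, `mismatch = 4`, `O1 = 8`, `E1 = 2`, `O2 = 80`,
#' `E2 = 1`. Under these values the long-gap regime becomes cheaper from
#' gap length 73 onward.
#'
#' @param match Score for identical bases.
#' @param mismatch Penalty (positive) for a substitution.
#' @param O1,E1 Gap open/extend of the short-gap regime.
#' @param O2,E2 Gap open/extend of the long-gap regime.
#' @param min_anchor_identity Minimum identity for an anchor placement.
#' @param max_interanchor_len Inter-anchor interval length above which the
#'   interval is left unaligned (the two sides become unaligned segments).
#' @param k Exact-seed length for anchor search.
#' @param max_keep_insert Longest child-specific insertion carried into a
#'   reconstructed ancestor sequence.
#' @param seed_max_occ Seeds occurring more often than this in the target
#'   are skipped as repetitive.
#' @param max_full_cells Largest DP matrix (cells) solved exactly; longer
#'   interval pairs use a banded DP around the diagonal.
#' @param min_junction_identity When composing projections, a junction
#'   segment present in both leaves is kept as an alignment only if its
#'   ungapped-column identity reaches this value; below it the segment is
#'   represented as a deletion plus an insertion (the two sides are treated
#'   as non-homologous).
#' @param band_width Half-width of the banded DP (on top of the length
#'   difference, which is always covered).
#' @param extension_band Band half-width used when aligning chain-end
#'   extensions, whose one-sided anchoring means the length difference
#'   does not bound interior indels; wide enough to cross structural
#'   events of a couple of kb.
#' @return A list of class `mga_params`.
#' @export
align_params <- function(match = 2, mismatch = 4,
                         O1 = 8, E1 = 2, O2 = 80, E2 = 1,
                         min_anchor_identity = 0.9,
                         max_interanchor_len = 20000L,
                         k = 15L,
                         max_keep_insert = 5000L,
                         seed_max_occ = 100L,
                         max_full_cells = 2.5e6,
                         band_width = 96L,
                         extension_band = 2048L,
                         min_junction_identity = 0.7) {
  if (any(c(O1, E1, O2, E2, mismatch) < 0)) abort("penalties must be >= 0")
  if (!(E2 < E1)) abort("the long-gap regime must extend more cheaply: E2 < E1")
  if (!(O2 > O1)) abort("the long-gap regime must open more expensively: O2 > O1")
  if (min_anchor_identity < 0 || min_anchor_identity > 1)
    abort("min_anchor_identity must be in [0, 1]")
  structure(list(match = match, mismatch = mismatch, O1 = O1, E1 = E1,
                 O2 = O2, E2 = E2,
                 min_anchor_identity = min_anchor_identity,
                 max_interanchor_len = as.integer(max_interanchor_len),
                 k = as.integer(k),
                 max_keep_insert = as.integer(max_keep_insert),
                 seed_max_occ = as.integer(seed_max_occ),
                 max_full_cells = max_full_cells,
                 band_width = as.integer(band_width),
                 extension_band = as.integer(extension_band),
                 min_junction_identity = min_junction_identity),
            class = "mga_params")
}

#' Read alignment parameters from a flat key: value text file
#' @param path Path to a text file of `key: value` lines.
#' @return An [align_params()] object.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- str_split(lines, ":", n = 2)
  keys <- trimws(map_chr(kv, 1))
  vals <- as.numeric(trimws(map_chr(kv, 2)))
  do.call(align_params, setNames(as.list(vals), keys))
}

#' Two-piece affine gap cost
#'
#' Cost of a gap run of length `L`: `min(O1 + E1*L, O2 + E2*L)`. The short
#' regime prices small gaps; the long regime, with high open and low
#' extend, prices long INDELs near-linearly.
#'
#' @param L Gap run length(s), `>= 1`.
#' @param params An [align_params()] object.
#' @return Numeric cost(s), vectorized over `L`.
#' @examples
#' p <- align_params()
#' gap_cost(1, p)    # 10
#' gap_cost(100, p)  # 180
#' @export
gap_cost <- function(L, params = align_params()) {
  if (any(L <= 0)) abort("gap length must be >= 1")
  pmin(params$O1 + params$E1 * L, params$O2 + params$E2 * L)
}
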