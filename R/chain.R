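#' Chain anchors into collinear blocks
#'
#' Maximum-score chaining by dynamic programming over anchors sorted by
#' reference start. A transition is allowed only between same-strand
#' anchors whose coordinates strictly increase on both genomes without
#' overlap (query coordinates decrease along minus-strand chains); its
#' penalty is `E2 * |ref_gap - qry_gap| + 1`. Chains are peeled off in
#' decreasing score order; anchors not in any chain of at least two
#' anchors, or in a chain with negative score, are discarded. Output
#' blocks are sorted by reference coordinate and non-overlapping on the
#' reference (overlaps resolved by keeping the higher-scoring block).
#'
#' @param anchors Anchor tibble from [match_anchors()] (deduplicated).
#' @param params An [align_params()] object.
#' @return List of collinear blocks; each is a list with `anchors` (tibble
#'   ordered by `ref_start`), `strand` and `chain_score`.
#' @export
chain_collinear <- function(anchors, params = align_params()) {
  if (!nrow(anchors)) return(list())
  blocks <- list()
  for (key in unique(paste(anchors$ref_seq, anchors$qry_seq, anchors$strand))) {
    d <- anchors[paste(anchors$ref_seq, anchors$qry_seq, anchors$strand) == key, ]
    d <- arrange(d, .data$ref_start, .data$qry_start)
    minus <- d$strand[1] == "-"
    score <- d$identity * (d$ref_end - d$ref_start + d$qry_end - d$qry_start) / 2
    n <- nrow(d)
    active <- rep(TRUE, n)
    repeat {
      idx <- which(active)
      if (!length(idx)) break
      dp <- score[idx]; prev <- rep(0L, length(idx))
      if (length(idx) > 1) {
        for (j in 2:length(idx)) {
          aj <- idx[j]
          for (i in 1:(j - 1)) {
            ai <- idx[i]
            rg <- d$ref_start[aj] - d$ref_end[ai]
            qg <- if (minus) d$qry_start[ai] - d$qry_end[aj]
                  else d$qry_start[aj] - d$qry_end[ai]
            if (rg < 0 || qg < 0) next
            cand <- dp[i] + score[aj] - (params$E2 * abs(rg - qg) + 1)
            if (cand > dp[j]) { dp[j] <- cand; prev[j] <- i }
          }
        }
      }
      # peel the best chain of >= 2 anchors; lone anchors are never emitted
      jcand <- which(prev != 0L)
      if (!length(jcand)) break
      jbest <- jcand[which.max(dp[jcand])]
      if (dp[jbest] < 0) break
      chain <- integer()
      j <- jbest
      while (j != 0L) { chain <- c(j, chain); j <- prev[j] }
      members <- idx[chain]
      active[members] <- FALSE
      blocks[[length(blocks) + 1L]] <- list(
        anchors = d[members, ], strand = d$strand[1], chain_score = dp[jbest])
    }
  }
  if (!length(blocks)) return(list())
  # resolve reference overlaps between blocks: higher score wins
  ord <- order(-map_dbl(blocks, "chain_score"))
  kept <- list()
  spans <- tibble(seq = character(), start = integer(), end = integer())
  for (b in blocks[ord]) {
    s <- b$anchors$ref_seq[1]
    lo <- min(b$anchors$ref_start); hi <- max(b$anchors$ref_end)
    clash <- any(spans$seq == s & spans$start < hi & spans$end > lo)
    if (clash) next
    spans <- bind_rows(spans, tibble(seq = s, start = lo, end = hi))
    kept[[length(kept) + 1L]] <- b
  }
  kept[order(map_chr(kept, ~ .x$anchors$ref_seq[1]),
             map_int(kept, ~ min(.x$anchors$ref_start)))]
}
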