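# Independent whole-run global-alignment oracle.
#
# Scores alignments directly as sum(substitutions) - sum(gap_cost(L)) over
# maximal gap runs, via a run-based DP: a gap state may only be entered
# from a state that does not extend the same run, so every maximal run is
# charged exactly once with its full two-piece cost. This shares no code
# with the five-state banded DP in the package.
oracle_align_score <- function(x, y, p = align_params()) {
  n <- nchar(x); m <- nchar(y)
  xc <- strsplit(x, "", fixed = TRUE)[[1]]
  yc <- strsplit(y, "", fixed = TRUE)[[1]]
  gc <- function(L) pmin(p$O1 + p$E1 * L, p$O2 + p$E2 * L)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)   # last column diagonal
  D <- matrix(NEG, n + 1, m + 1)   # last run consumed x (gap in y)
  I <- matrix(NEG, n + 1, m + 1)   # last run consumed y (gap in x)
  M[1, 1] <- 0
  for (i in 0:n) for (j in 0:m) {
    if (i > 0 && j > 0) {
      s <- if (xc[i] == yc[j]) p$match else -p$mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], D[i, j], I[i, j])
    }
    if (i > 0) {
      l <- 1:i
      D[i + 1, j + 1] <- max(pmax(M[i + 1 - l, j + 1], I[i + 1 - l, j + 1]) - gc(l))
    }
    if (j > 0) {
      l <- 1:j
      I[i + 1, j + 1] <- max(pmax(M[i + 1, j + 1 - l], D[i + 1, j + 1 - l]) - gc(l))
    }
  }
  max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
}

# exhaustive enumeration of every global alignment (tiny n only): the
# ground truth the run-DP oracle itself is validated against
enumerate_align_score <- function(x, y, p = align_params()) {
  gc <- function(L) min(p$O1 + p$E1 * L, p$O2 + p$E2 * L)
  best <- -Inf
  rec <- function(i, j, cols) {
    if (i > nchar(x) && j > nchar(y)) {
      sc <- 0
      runs <- rle(cols)
      for (k in seq_along(runs$values)) {
        v <- runs$values[k]; L <- runs$lengths[k]
        if (v == "M") {
          } else sc <- sc - gc(L)
      }
      idx <- which(cols == "M")
      xi <- cumsum(cols != "I"); yi <- cumsum(cols != "D")
      for (k in idx)
        sc <- sc + if (substr(x, xi[k], xi[k]) == substr(y, yi[k], yi[k])) p$match else -p$mismatch
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    if (i <= nchar(x) && j <= nchar(y)) rec(i + 1, j + 1, c(cols, "M"))
    if (i <= nchar(x)) rec(i + 1, j, c(cols, "D"))
    if (j <= nchar(y)) rec(i, j + 1, c(cols, "I"))
    invisible(NULL)
  }
  rec(1, 1, character(0))
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
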