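#' Global alignment of one interval pair under the two-piece gap cost
#'
#' Optimal global alignment maximizing
#' `sum(match/mismatch) - sum(gap_cost(L))` over maximal gap runs, computed
#' by dynamic programming with two gap states per sequence (four gap
#' matrices plus one match matrix). Ties are broken deterministically:
#' diagonal first, then gap-in-qry, then gap-in-ref; within a gap state,
#' run extension beats re-opening. Either sequence may be empty (the other
#' is aligned as one pure gap run).
#'
#' Interval pairs whose full DP matrix exceeds `params$max_full_cells`
#' are solved with a banded DP that always covers the length difference
#' plus `params$band_width` diagonals; at the divergence levels the
#' anchor-chained pipeline produces, the band contains the optimum.
#'
#' @param ref_seq,qry_seq Nucleotide strings (`ACGTN`; possibly empty).
#' @param params An [align_params()] object.
#' @param band Optional band half-width override; `-1` forces the full DP.
#' @return List with `ref` and `qry` (gapped strings) and `score`.
#' @examples
#' align_interval("ACGT", "ACGT")$score  # 8 with defaults
#' @export
align_interval <- function(ref_seq, qry_seq, params = align_params(), band = NULL) {
  for (s in c(ref_seq, qry_seq))
    if (nchar(s) && str_detect(s, "[^ACGTN]"))
      abort("sequences must contain only A, C, G, T, N")
  n <- nchar(ref_seq); m <- nchar(qry_seq)
  if (is.null(band)) {
    full_cells <- (as.double(n) + 1) * (as.double(m) + 1)
    band <- if (full_cells <= params$max_full_cells) -1L else params$band_width
  }
  res <- cpp_twopiece_align(ref_seq, qry_seq, params$match, params$mismatch,
                            params$O1, params$E1, params$O2, params$E2,
                            as.integer(band), 2e8)
  list(ref = res$ax, qry = res$ay, score = res$score)
}

# score an explicit alignment under the two-piece model (columns plus
# whole gap runs); used where alignments are assembled rather than traced
score_alignment <- function(ax, ay, params) {
  if (!nchar(ax)) return(0)
  a <- strsplit(ax, "", fixed = TRUE)[[1]]
  b <- strsplit(ay, "", fixed = TRUE)[[1]]
  type <- ifelse(a == "-", 1L, ifelse(b == "-", 2L, 0L))
  al <- type == 0L
  sub <- sum(a[al] == b[al]) * params$match -
    sum(a[al] != b[al]) * params$mismatch
  r <- rle(type)
  sub - sum(gap_cost(r$lengths[r$values != 0L], params))
}

# alignment of one interval pair with recursive local anchoring: exact
# 31-mer runs unique within BOTH interval sequences are chained (longest
# non-conflicting set) and the segments between them aligned recursively.
# This keeps long, repeat-dense intervals positionally pinned where a
# plain banded DP cannot represent a multi-indel layout. Falls back to the
# plain DP (with a widened band) when no local anchors exist.
align_interval_chained <- function(ref_seq, qry_seq, params, depth = 6L) {
  n <- nchar(ref_seq); m <- nchar(qry_seq)
  # a non-homologous segment pair is represented as a deletion followed by
  # an insertion rather than as meaningless mismatch columns
  gate <- function(al) {
    if (n < 30 || m < 30) return(al)
    idn <- alignment_identity(al$ref, al$qry)
    if (!is.na(idn$from) && idn$identity >= params$min_junction_identity) return(al)
    ax <- paste0(ref_seq, strrep("-", m))
    ay <- paste0(strrep("-", n), qry_seq)
    list(ref = ax, qry = ay, score = score_alignment(ax, ay, params))
  }
  if (n == 0 || m == 0 || (n <= 600 && m <= 600) || depth <= 0L)
    return(gate(align_interval(ref_seq, qry_seq, params)))
  runs <- local_unique_runs(ref_seq, qry_seq, min_len = 50L)
  if (!nrow(runs)) {
    band <- {
      full_cells <- (as.double(n) + 1) * (as.double(m) + 1)
      if (full_cells <= params$max_full_cells) -1L
      else min(max(params$band_width, params$extension_band),
               as.integer(1.5e8 / (max(n, m) + 1)))
    }
    return(gate(align_interval(ref_seq, qry_seq, params, band = band)))
  }
  runs <- chain_runs(runs)
  segs_r <- character(0); segs_q <- character(0)
  r_cur <- 0L; q_cur <- 0L
  for (i in seq_len(nrow(runs) + 1L)) {
    if (i <= nrow(runs)) { r2 <- runs$rs[i]; q2 <- runs$qs[i] }
    else { r2 <- n; q2 <- m }
    sub <- align_interval_chained(substr(ref_seq, r_cur + 1L, r2),
                                  substr(qry_seq, q_cur + 1L, q2),
                                  params, depth - 1L)
    segs_r <- c(segs_r, sub$ref); segs_q <- c(segs_q, sub$qry)
    if (i <= nrow(runs)) {
      exact <- substr(ref_seq, runs$rs[i] + 1L, runs$rs[i] + runs$len[i])
      segs_r <- c(segs_r, exact); segs_q <- c(segs_q, exact)
      r_cur <- runs$rs[i] + runs$len[i]; q_cur <- runs$qs[i] + runs$len[i]
    }
  }
  ax <- paste(segs_r, collapse = ""); ay <- paste(segs_q, collapse = "")
  list(ref = ax, qry = ay, score = score_alignment(ax, ay, params))
}

# maximal runs of exact 31-mers unique within both sequences (0-based
# starts); the uniqueness is local to this interval pair
local_unique_runs <- function(ref_seq, qry_seq, min_len = 50L) {
  empty <- tibble(rs = integer(), qs = integer(), len = integer())
  if (nchar(ref_seq) < 31 || nchar(qry_seq) < 31) return(empty)
  self <- cpp_seed_hits(ref_seq, ref_seq, 31L, 1L)[[1]]
  hits <- cpp_seed_hits(ref_seq, qry_seq, 31L, 1L)[[1]]
  if (!nrow(hits) || !nrow(self)) return(empty)
  hits <- hits[hits[, 1] %in% self[, 1], , drop = FALSE]
  if (!nrow(hits)) return(empty)
  ord <- order(hits[, 1], hits[, 2])
  qp <- hits[ord, 1]; tp <- hits[ord, 2]
  run <- cumsum(c(TRUE, !(diff(qp) == 1L & diff(tp) == 1L)))
  out <- lapply(split(seq_along(run), run), function(ix) {
    len <- length(ix) - 1L + 31L
    if (len < min_len) return(NULL)
    tibble(rs = qp[ix[1]], qs = tp[ix[1]], len = len)
  })
  res <- bind_rows(out)
  if (!nrow(res)) empty else res
}

# longest total-length chain of runs, strictly monotone and non-overlapping
# on both sequences (quadratic DP; run counts are small)
chain_runs <- function(runs) {
  runs <- runs[order(runs$rs), ]
  nr <- nrow(runs)
  dp <- as.numeric(runs$len); prev <- rep(0L, nr)
  if (nr > 1) for (j in 2:nr) for (i in 1:(j - 1)) {
    if (runs$rs[i] + runs$len[i] <= runs$rs[j] &&
        runs$qs[i] + runs$len[i] <= runs$qs[j]) {
      cand <- dp[i] + runs$len[j]
      if (cand > dp[j]) { dp[j] <- cand; prev[j] <- i }
    }
  }
  j <- which.max(dp); chain <- integer(0)
  while (j != 0L) { chain <- c(j, chain); j <- prev[j] }
  runs[chain, ]
}

# score-improving polish of an assembled alignment: where two gap runs in
# the same row flank a tiny aligned island, merging them into one long run
# (the island's other-row bases becoming a short opposite gap) often scores
# higher under the two-piece cost — the layout a single global DP would
# have chosen, which piecewise assembly can miss. Merges are applied only
# when they strictly improve the score, so the result is deterministic and
# never worse.
polish_alignment <- function(ax, ay, params, max_island = 3L) {
  a <- strsplit(ax, "", fixed = TRUE)[[1]]
  b <- strsplit(ay, "", fixed = TRUE)[[1]]
  for (pass in 1:10) {
    type <- ifelse(a == "-", 1L, ifelse(b == "-", 2L, 0L))
    r <- rle(type)
    if (length(r$values) < 3) break
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    improved <- FALSE
    i <- 2L
    while (i < length(r$values)) {
      if (r$values[i] == 0L && r$lengths[i] <= max_island &&
          r$values[i - 1] == r$values[i + 1] && r$values[i - 1] != 0L) {
        L1 <- r$lengths[i - 1]; L2 <- r$lengths[i + 1]; len <- r$lengths[i]
        isl <- starts[i]:ends[i]
        s <- sum(ifelse(a[isl] == b[isl], params$match, -params$mismatch))
        cost_now <- gap_cost(L1, params) + gap_cost(L2, params) - s
        cost_merged <- gap_cost(L1 + len + L2, params) + gap_cost(len, params)
        if (cost_merged < cost_now - 1e-9) {
          seg <- starts[i - 1]:ends[i + 1]
          if (r$values[i - 1] == 2L) {  # gaps in the second row
            new_a <- c(a[seg][a[seg] != "-"], rep("-", len))
            new_b <- c(rep("-", L1 + len + L2), b[isl])
          } else {                      # gaps in the first row
            new_a <- c(a[isl], rep("-", L1 + len + L2))
            new_b <- c(rep("-", len), b[seg][b[seg] != "-"])
          }
          a <- c(a[seq_len(starts[i - 1] - 1L)], new_a,
                 if (ends[i + 1] < length(a)) a[(ends[i + 1] + 1L):length(a)])
          b <- c(b[seq_len(starts[i - 1] - 1L)], new_b,
                 if (ends[i + 1] < length(b)) b[(ends[i + 1] + 1L):length(b)])
          improved <- TRUE
          break  # recompute run structure
        }
      }
      i <- i + 1L
    }
    if (!improved) break
  }
  list(ref = paste(a, collapse = ""), qry = paste(b, collapse = ""))
}

# banded alignment used for anchor intervals (similar lengths expected)
align_banded <- function(ref_seq, qry_seq, params) {
  n <- nchar(ref_seq); m <- nchar(qry_seq)
  w <- max(params$band_width, ceiling(0.1 * min(n, m)))
  align_interval(ref_seq, qry_seq, params, band = w)
}

# identity of an alignment after trimming terminal columns where one row
# is gapped; identity = matched fraction of ungapped columns between the
# first and last aligned column (used to gate whether an interval pair is
# homologous at all)
alignment_identity <- function(ax, ay) {
  a <- strsplit(ax, "", fixed = TRUE)[[1]]
  b <- strsplit(ay, "", fixed = TRUE)[[1]]
  core <- which(a != "-" & b != "-")
  if (!length(core)) return(list(identity = 0, from = NA, to = NA))
  cols <- core[1]:core[length(core)]
  al <- which(a[cols] != "-" & b[cols] != "-")
  list(identity = sum(a[cols][al] == b[cols][al]) / length(al),
       from = core[1], to = core[length(core)])
}

# maximum-scoring contiguous segment of an alignment (runs as units: an
# aligned column scores +match/-mismatch, a gap run scores -gap_cost(L)).
# Trims terminally-tied junk such as a lone end base matched across a long
# gap, which a global DP keeps at equal score. Returns the column range of
# the best segment and its identity over aligned columns, or NA when no
# positive-scoring segment exists.
alignment_core <- function(ax, ay, params) {
  a <- strsplit(ax, "", fixed = TRUE)[[1]]
  b <- strsplit(ay, "", fixed = TRUE)[[1]]
  if (!length(a)) return(list(identity = 0, from = NA, to = NA))
  type <- ifelse(a == "-", 1L, ifelse(b == "-", 2L, 0L))
  r <- rle(type)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  parts <- lapply(seq_along(r$values), function(i) {
    if (r$values[i] == 0L) {
      j <- starts[i]:ends[i]  # aligned columns are separate units
      list(score = ifelse(a[j] == b[j], params$match, -params$mismatch),
           from = j, to = j)
    } else {
      list(score = -gap_cost(r$lengths[i], params),
           from = starts[i], to = ends[i])
    }
  })
  uscore <- unlist(lapply(parts, `[[`, "score"))
  ufrom <- unlist(lapply(parts, `[[`, "from"))
  uto <- unlist(lapply(parts, `[[`, "to"))
  # Kadane over units
  best <- 0; bi <- NA; bj <- NA; cur <- 0; ci <- 1L
  for (k in seq_along(uscore)) {
    if (cur <= 0) { cur <- 0; ci <- k }
    cur <- cur + uscore[k]
    if (cur > best) { best <- cur; bi <- ci; bj <- k }
  }
  if (is.na(bi)) return(list(identity = 0, from = NA, to = NA))
  cols <- ufrom[bi]:uto[bj]
  al <- which(a[cols] != "-" & b[cols] != "-")
  list(identity = sum(a[cols][al] == b[cols][al]) / length(al),
       from = ufrom[bi], to = uto[bj])
}
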