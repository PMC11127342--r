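#' Extract anchor query sequences (spliced CDS per gene)
#'
#' One spliced CDS per gene, taken from the gene's longest mRNA (by total
#' CDS length). Minus-strand CDS are reverse-complemented to coding
#' orientation. The genomic span and exon intervals are retained for
#' coordinate mapping.
#'
#' @param ref An [mga_genome()].
#' @param ref_ann An [mga_features()] annotation of `ref`.
#' @return Tibble with one row per anchor query: `feature_id`, `ref_seq`,
#'   `ref_start`, `ref_end` (genomic span, 0-based half-open), `strand`,
#'   `query` (spliced CDS string) and `exons` (list of start/end tibbles).
#' @export
extract_anchor_queries <- function(ref, ref_ann) {
  stopifnot(inherits(ref, "mga_genome"), inherits(ref_ann, "mga_features"))
  cds <- ref_ann[ref_ann$type == "CDS", ]
  if (!nrow(cds))
    return(tibble(feature_id = character(), ref_seq = character(),
                  ref_start = integer(), ref_end = integer(), strand = character(),
                  query = character(), exons = list()))
  mrna <- ref_ann[ref_ann$type == "mRNA", ]
  gene_of <- setNames(mrna$parent_id, mrna$feature_id)
  by_mrna <- split(cds, cds$parent_id)
  tot <- map_int(by_mrna, ~ sum(.x$end - .x$start))
  # longest mRNA per gene; ties broken lexicographically by mRNA id
  info <- tibble(mrna_id = names(by_mrna), total = unname(tot),
                 gene = unname(gene_of[names(by_mrna)]))
  info$gene[is.na(info$gene)] <- info$mrna_id[is.na(info$gene)]  # CDS parented by gene
  info <- arrange(info, .data$gene, desc(.data$total), .data$mrna_id)
  info <- info[!duplicated(info$gene), ]
  rows <- lapply(info$mrna_id, function(id) {
    ex <- arrange(by_mrna[[id]], .data$start)
    spliced <- paste0(map_chr(seq_len(nrow(ex)),
                              ~ seq_slice(ref, ex$seq[.x], ex$start[.x], ex$end[.x])),
                      collapse = "")
    strand <- ex$strand[1]
    if (strand == "-") spliced <- revcomp(spliced)
    tibble(feature_id = id, ref_seq = ex$seq[1],
           ref_start = min(ex$start), ref_end = max(ex$end),
           strand = strand, query = spliced,
           exons = list(ex[c("start", "end")]))
  })
  bind_rows(rows)
}

# cluster seed hits of one query into candidate placements
cluster_seeds <- function(hits, qlen) {
  if (!nrow(hits)) return(list())
  ord <- order(hits[, 2], hits[, 1])
  qp <- hits[ord, 1]; tp <- hits[ord, 2]
  diag <- tp - qp
  tol <- 0.3 * qlen + 50
  cl <- cumsum(c(TRUE, diff(tp) > qlen | abs(diff(diag)) > tol))
  lapply(split(seq_along(cl), cl), function(ix) list(qp = qp[ix], tp = tp[ix]))
}

#' Locate anchor queries in another genome
#'
#' Each spliced-CDS query is placed by exact k-mer seeding followed by
#' banded extension over the seeded window under the two-piece gap score.
#' Placements with identity below `params$min_anchor_identity` are
#' discarded; a query with more than 3 near-best placements (within 2%
#' identity of the best) is dropped entirely as repetitive-ambiguous.
#' Both orientations are searched; minus-strand placements are recorded
#' with `strand == "-"`.
#'
#' @param queries Output of [extract_anchor_queries()].
#' @param qry An [mga_genome()] to search.
#' @param params An [align_params()] object.
#' @return Tibble of anchors: `feature_id`, `ref_seq`, `ref_start`,
#'   `ref_end`, `qry_seq`, `qry_start`, `qry_end`, `strand`, `identity`
#'   (all intervals 0-based half-open on the + strand).
#' @export
match_anchors <- function(queries, qry, params = align_params()) {
  stopifnot(inherits(qry, "mga_genome"))
  empty <- tibble(feature_id = character(), ref_seq = character(),
                  ref_start = integer(), ref_end = integer(),
                  qry_seq = character(), qry_start = integer(), qry_end = integer(),
                  strand = character(), identity = double())
  if (!nrow(queries)) return(empty)
  placements <- vector("list", 64L); np <- 0L
  qstr <- queries$query
  rstr <- revcomp(qstr)
  for (seq_name in names(qry$seq)) {
    target <- qry$seq[[seq_name]]
    for (ori in c("+", "-")) {
      qs <- if (ori == "+") qstr else rstr
      hits <- cpp_seed_hits(qs, target, params$k, params$seed_max_occ)
      for (qi in seq_along(hits)) {
        qlen <- nchar(qs[qi])
        for (cl in cluster_seeds(hits[[qi]], qlen)) {
          slack <- as.integer(20 + 0.05 * qlen)
          w1 <- max(0L, min(cl$tp) - min(cl$qp) - slack)
          w2 <- min(nchar(target),
                    max(cl$tp) + params$k + (qlen - max(cl$qp) - params$k) + slack)
          if (w2 <= w1) next
          window <- substr(target, w1 + 1L, w2)
          al <- align_banded(window, qs[qi], params)
          idn <- alignment_core(al$ref, al$qry, params)
          if (is.na(idn$from) || idn$identity < params$min_anchor_identity) next
          # placement interval = window positions covered by the trimmed core
          wchars <- strsplit(al$ref, "", fixed = TRUE)[[1]]
          qchars <- strsplit(al$qry, "", fixed = TRUE)[[1]]
          wpos <- cumsum(wchars != "-")
          p1 <- w1 + wpos[idn$from] - (wchars[idn$from] != "-")
          p2 <- w1 + wpos[idn$to]
          # terminal-tie rescue: when the DP parks the query's last (or
          # first) bases beyond a gap at equal score, the trimmed core
          # loses them; re-attach when they also match contiguously
          qafter <- sum(qchars != "-" & seq_along(qchars) > idn$to)
          if (qafter > 0 && qafter <= 5) {
            tailq <- substr(qs[qi], nchar(qs[qi]) - qafter + 1L, nchar(qs[qi]))
            if (substr(target, p2 + 1L, p2 + qafter) == tailq) p2 <- p2 + qafter
          }
          qbefore <- sum(qchars != "-" & seq_along(qchars) < idn$from)
          if (qbefore > 0 && qbefore <= 5) {
            headq <- substr(qs[qi], 1L, qbefore)
            if (p1 - qbefore >= 0 &&
                substr(target, p1 - qbefore + 1L, p1) == headq) p1 <- p1 - qbefore
          }
          np <- np + 1L
          if (np > length(placements)) placements <- c(placements, vector("list", length(placements)))
          placements[[np]] <- tibble(
            feature_id = queries$feature_id[qi],
            ref_seq = queries$ref_seq[qi],
            ref_start = queries$ref_start[qi], ref_end = queries$ref_end[qi],
            qry_seq = seq_name, qry_start = as.integer(p1), qry_end = as.integer(p2),
            strand = if (queries$strand[qi] == "-") {
              if (ori == "+") "-" else "+"
            } else ori,
            identity = idn$identity)
        }
      }
    }
  }
  if (!np) return(empty)
  anc <- distinct(bind_rows(placements[seq_len(np)]))
  out <- lapply(split(anc, anc$feature_id), function(d) {
    best <- max(d$identity)
    near <- d[d$identity >= best - 0.02, ]
    if (nrow(near) > 3) return(NULL)  # repetitive-ambiguous: drop the CDS
    near
  })
  res <- bind_rows(out)
  if (!nrow(res)) return(empty)
  arrange(res, .data$ref_seq, .data$ref_start, .data$qry_seq, .data$qry_start)
}

# anchors from maximal runs of exact 31-mers unique in BOTH genomes, kept
# when >= min_len and treated as identity-1 anchors; they pin the
# alignment between gene anchors and are the sole anchor source for
# unannotated references
unique_match_anchors <- function(ref, qry, params, min_len = 200L) {
  out <- list()
  for (rs in names(ref$seq)) {
    self <- cpp_seed_hits(ref$seq[[rs]], ref$seq[[rs]], 31L, 1L)[[1]]
    ref_unique <- self[, 1]  # seed positions whose 31-mer is unique in ref
    for (qs_name in names(qry$seq)) {
      hits <- cpp_seed_hits(ref$seq[[rs]], qry$seq[[qs_name]], 31L, 1L)[[1]]
      if (!nrow(hits)) next
      keep <- hits[, 1] %in% ref_unique
      hits <- hits[keep, , drop = FALSE]
      if (!nrow(hits)) next
      ord <- order(hits[, 1], hits[, 2])
      qp <- hits[ord, 1]; tp <- hits[ord, 2]
      new_run <- c(TRUE, !(diff(qp) == 1L & diff(tp) == 1L))
      run <- cumsum(new_run)
      for (ix in split(seq_along(run), run)) {
        len <- length(ix) - 1L + 31L
        if (len < min_len) next
        out[[length(out) + 1L]] <- tibble(
          feature_id = sprintf("uniq-%s-%d", rs, qp[ix[1]]),
          ref_seq = rs, ref_start = qp[ix[1]], ref_end = qp[ix[1]] + len,
          qry_seq = qs_name, qry_start = tp[ix[1]], qry_end = tp[ix[1]] + len,
          strand = "+", identity = 1)
      }
    }
  }
  if (!length(out))
    return(match_anchors(tibble(feature_id = character(), query = character()),
                         qry, params))
  arrange(bind_rows(out), .data$ref_seq, .data$ref_start)
}
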