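#' Anchor-based collinear pairwise genome alignment
#'
#' Full pairwise alignment of two genomes: spliced-CDS anchors are located
#' in the query ([extract_anchor_queries()], [match_anchors()]), chained
#' into collinear blocks ([chain_collinear()]), and every anchor and
#' inter-anchor interval is aligned globally under the two-piece affine
#' gap cost. Each collinear chain is emitted as one MAF block; an
#' inter-anchor interval longer than `params$max_interanchor_len` on
#' either side splits the chain into two blocks and is left unaligned.
#' Minus-strand (inversion) chains are detected but left unaligned, so all
#' emitted blocks are on the + strand of both genomes. If the reference
#' has no CDS annotation, anchors fall back to maximal unique exact
#' matches of at least 200 bp.
#'
#' @param ref Reference [mga_genome()] (alignment reference of the pair).
#' @param ref_ann [mga_features()] for `ref` (may contain zero CDS).
#' @param qry Query [mga_genome()].
#' @param params An [align_params()] object.
#' @return List of two-row [mga_block()] objects, reference row first,
#'   covering disjoint reference intervals.
#' @export
align_genomes <- function(ref, ref_ann, qry, params = align_params()) {
  queries <- extract_anchor_queries(ref, ref_ann)
  anchors <- if (nrow(queries)) match_anchors(queries, qry, params)
             else tibble()
  # unique exact matches pin the alignment between gene anchors (and are
  # the sole anchor source when the reference has no CDS annotation)
  uniq <- unique_match_anchors(ref, qry, params)
  if (nrow(anchors) && nrow(uniq)) {
    clash <- map_lgl(seq_len(nrow(uniq)), function(i) {
      any(anchors$ref_seq == uniq$ref_seq[i] &
            anchors$ref_start < uniq$ref_end[i] & anchors$ref_end > uniq$ref_start[i]) ||
        any(anchors$qry_seq == uniq$qry_seq[i] &
              anchors$qry_start < uniq$qry_end[i] & anchors$qry_end > uniq$qry_start[i])
    })
    uniq <- uniq[!clash, ]
  }
  anchors <- distinct(bind_rows(anchors, uniq))
  chains <- chain_collinear(anchors, params)
  chains <- chains[map_chr(chains, "strand") == "+"]
  # reference spans of all chains, for overlap checks when extending
  chain_spans <- if (length(chains)) {
    tibble(seq = map_chr(chains, ~ .x$anchors$ref_seq[1]),
           start = map_int(chains, ~ min(.x$anchors$ref_start)),
           end = map_int(chains, ~ max(.x$anchors$ref_end)))
  } else tibble(seq = character(), start = integer(), end = integer())
  blocks <- list()
  for (ch in chains) {
    a <- ch$anchors
    rs <- a$ref_seq[1]; qs <- a$qry_seq[1]
    segs_ref <- character(); segs_qry <- character()
    open_ref0 <- a$ref_start[1]; open_qry0 <- a$qry_start[1]
    flush <- function(ref0, qry0) {
      if (!length(segs_ref)) return(invisible(NULL))
      pol <- polish_alignment(paste(segs_ref, collapse = ""),
                              paste(segs_qry, collapse = ""), params)
      ref_text <- pol$ref
      qry_text <- pol$qry
      rsize <- nchar(gsub("-", "", ref_text, fixed = TRUE))
      qsize <- nchar(gsub("-", "", qry_text, fixed = TRUE))
      blocks[[length(blocks) + 1L]] <<- mga_block(
        tibble(genome = c(ref$genome_id, qry$genome_id),
               seq = c(rs, qs), start = c(ref0, qry0), size = c(rsize, qsize),
               strand = "+", src_size = c(nchar(ref$seq[[rs]]), nchar(qry$seq[[qs]]))),
        c(ref_text, qry_text))
      invisible(NULL)
    }
    for (i in seq_len(nrow(a))) {
      if (i > 1) {
        r1 <- a$ref_end[i - 1]; r2 <- a$ref_start[i]
        q1 <- a$qry_end[i - 1]; q2 <- a$qry_start[i]
        if ((r2 - r1) > params$max_interanchor_len ||
            (q2 - q1) > params$max_interanchor_len) {
          # unalignable interval: close the current block, skip the interval
          flush(open_ref0, open_qry0)
          segs_ref <- character(); segs_qry <- character()
          open_ref0 <- a$ref_start[i]; open_qry0 <- a$qry_start[i]
        } else if (r2 > r1 || q2 > q1) {
          # align_interval_chained gates non-homologous segment pairs
          # internally (they come back as a deletion plus an insertion)
          al <- align_interval_chained(seq_slice(ref, rs, r1, r2),
                                       seq_slice(qry, qs, q1, q2), params)
          segs_ref <- c(segs_ref, al$ref); segs_qry <- c(segs_qry, al$qry)
        }
      }
      al <- align_banded(seq_slice(ref, rs, a$ref_start[i], a$ref_end[i]),
                         seq_slice(qry, qs, a$qry_start[i], a$qry_end[i]), params)
      segs_ref <- c(segs_ref, al$ref); segs_qry <- c(segs_qry, al$qry)
    }
    flush(open_ref0, open_qry0)
  }
  c(blocks, extend_chain_ends(ref, qry, chains, chain_spans, params))
}

# align the homologous segments outside the outermost anchors of each
# chain group and between consecutive monotone chains, so coverage reaches
# the sequence ends; extensions never overlap another chain's reference
# span and are capped at max_interanchor_len on both sides
extend_chain_ends <- function(ref, qry, chains, chain_spans, params) {
  out <- list()
  add_seg <- function(rs, qs, r1, r2, q1, q2, anchored = c("left", "right", "both")) {
    anchored <- match.arg(anchored)
    # keep the two sides comparable so unalignable overhang stays bounded
    if (anchored == "right") {
      r1 <- max(r1, r2 - ((q2 - q1) + 1000L)); q1 <- max(q1, q2 - ((r2 - r1) + 1000L))
    } else if (anchored == "left") {
      r2 <- min(r2, r1 + ((q2 - q1) + 1000L)); q2 <- min(q2, q1 + ((r2 - r1) + 1000L))
    }
    if (r2 - r1 <= 0 || q2 - q1 <= 0) return(invisible(NULL))
    if (r2 - r1 > params$max_interanchor_len || q2 - q1 > params$max_interanchor_len)
      return(invisible(NULL))
    clash <- any(chain_spans$seq == rs & chain_spans$start < r2 & chain_spans$end > r1)
    if (clash) return(invisible(NULL))
    ra <- seq_slice(ref, rs, r1, r2); qa <- seq_slice(qry, qs, q1, q2)
    # an extension is unanchored on one side, so its length difference says
    # nothing about interior indels; when the full DP is too large, use a
    # band wide enough to cross structural events of a few kb
    full_cells <- (nchar(ra) + 1) * (nchar(qa) + 1)
    ext_band <- if (full_cells <= params$max_full_cells) -1L
                else max(params$band_width, params$extension_band)
    al <- align_interval(ra, qa, params, band = ext_band)
    al <- polish_alignment(al$ref, al$qry, params)
    # extensions reach beyond the anchored span: keep only the
    # best-scoring core, and only when it shows real homology
    idn <- alignment_core(al$ref, al$qry, params)
    if (is.na(idn$from) || idn$identity < params$min_junction_identity)
      return(invisible(NULL))
    a <- strsplit(al$ref, "", fixed = TRUE)[[1]]
    b <- strsplit(al$qry, "", fixed = TRUE)[[1]]
    cols <- idn$from:idn$to
    roff <- sum(a[seq_len(idn$from - 1L)] != "-")
    qoff <- sum(b[seq_len(idn$from - 1L)] != "-")
    rsize <- sum(a[cols] != "-"); qsize <- sum(b[cols] != "-")
    out[[length(out) + 1L]] <<- mga_block(
      tibble(genome = c(ref$genome_id, qry$genome_id), seq = c(rs, qs),
             start = c(r1 + roff, q1 + qoff), size = c(rsize, qsize), strand = "+",
             src_size = c(nchar(ref$seq[[rs]]), nchar(qry$seq[[qs]]))),
      c(paste(a[cols], collapse = ""), paste(b[cols], collapse = "")))
    invisible(NULL)
  }
  grp <- split(chains, map_chr(chains, ~ paste(.x$anchors$ref_seq[1],
                                               .x$anchors$qry_seq[1])))
  for (g in grp) {
    g <- g[order(map_int(g, ~ min(.x$anchors$ref_start)))]
    rs <- g[[1]]$anchors$ref_seq[1]; qs <- g[[1]]$anchors$qry_seq[1]
    first <- g[[1]]$anchors; last <- g[[length(g)]]$anchors
    r0 <- min(first$ref_start); q0 <- min(first$qry_start)
    add_seg(rs, qs, max(0L, r0 - params$max_interanchor_len), r0,
            max(0L, q0 - params$max_interanchor_len), q0, anchored = "right")
    r1 <- max(last$ref_end); q1 <- max(last$qry_end)
    add_seg(rs, qs, r1, min(nchar(ref$seq[[rs]]), r1 + params$max_interanchor_len),
            q1, min(nchar(qry$seq[[qs]]), q1 + params$max_interanchor_len),
            anchored = "left")
    if (length(g) > 1) for (i in 1:(length(g) - 1)) {
      a1 <- g[[i]]$anchors; a2 <- g[[i + 1]]$anchors
      if (min(a2$qry_start) >= max(a1$qry_end))  # monotone neighbours: bridge
        add_seg(rs, qs, max(a1$ref_end), min(a2$ref_start),
                max(a1$qry_end), min(a2$qry_start), anchored = "both")
    }
  }
  out
}
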