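# Build two-row + strand alignment blocks from co-mapped coordinate pairs.
# pa/pb are parallel 1-based positions in the ref and qry sequences. Runs
# are split where either coordinate fails to increase or where the
# unrepresented jump on either side exceeds max_interanchor_len. Inside a
# run, junction segments present on only one side become pure gap runs;
# segments present on both sides are re-aligned with align_interval so the
# emitted columns remain substring-faithful on both genomes.
pairs_to_blocks <- function(pa, pb, ref_genome, ref_seqname, qry_genome, qry_seqname,
                            params) {
  if (!length(pa)) return(list())
  rseq <- ref_genome$seq[[ref_seqname]]
  qseq <- qry_genome$seq[[qry_seqname]]
  da <- diff(pa); db <- diff(pb)
  split_here <- da <= 0 | db <= 0 |
    pmax(da, db) - 1L > params$max_interanchor_len
  run <- cumsum(c(TRUE, split_here))
  blocks <- list()
  for (ix in split(seq_along(pa), run)) {
    a <- pa[ix]; b <- pb[ix]
    jr <- which(diff(a) > 1L | diff(b) > 1L)  # junction before a[jr + 1]
    bounds <- c(0L, jr, length(a))
    pieces_r <- character(0); pieces_q <- character(0)
    for (s in seq_len(length(bounds) - 1L)) {
      j1 <- bounds[s] + 1L; j2 <- bounds[s + 1L]
      if (s > 1) {  # junction between a[j1-1] and a[j1]
        ra <- substr(rseq, a[j1 - 1L] + 1L, a[j1] - 1L)
        qb <- substr(qseq, b[j1 - 1L] + 1L, b[j1] - 1L)
        if (nchar(ra) && nchar(qb)) {
          # non-homologous junction pairs come back from the chained
          # aligner as a deletion plus an insertion
          al <- align_interval_chained(ra, qb, params)
          pieces_r <- c(pieces_r, al$ref); pieces_q <- c(pieces_q, al$qry)
        } else if (nchar(ra)) {
          pieces_r <- c(pieces_r, ra)
          pieces_q <- c(pieces_q, strrep("-", nchar(ra)))
        } else if (nchar(qb)) {
          pieces_r <- c(pieces_r, strrep("-", nchar(qb)))
          pieces_q <- c(pieces_q, qb)
        }
      }
      pieces_r <- c(pieces_r, substr(rseq, a[j1], a[j2]))
      pieces_q <- c(pieces_q, substr(qseq, b[j1], b[j2]))
    }
    pol <- polish_alignment(paste(pieces_r, collapse = ""),
                            paste(pieces_q, collapse = ""), params)
    rtext <- pol$ref; qtext <- pol$qry
    blocks[[length(blocks) + 1L]] <- mga_block(
      tibble(genome = c(ref_genome$genome_id, qry_genome$genome_id),
             seq = c(ref_seqname, qry_seqname),
             start = c(a[1] - 1L, b[1] - 1L),
             size = c(a[length(a)] - a[1] + 1L, b[length(b)] - b[1] + 1L),
             strand = "+",
             src_size = c(nchar(rseq), nchar(qseq))),
      c(rtext, qtext))
  }
  blocks
}

# map every position of `from` (an ancestor node) down the hierarchy to the
# given leaf; returns per from-sequence list(seq=, pos=) in 0-based leaf
# coordinates (leaf sequence indexed into the leaf's sequence names)
descend_map <- function(h, from_id, leaf_id, path) {
  node <- h$nodes[[from_id]]
  cur <- lapply(names(node$genome$seq), function(nm) {
    len <- nchar(node$genome$seq[[nm]])
    list(seq = rep(match(nm, names(node$genome$seq)), len), pos = 0:(len - 1L))
  })
  names(cur) <- names(node$genome$seq)
  at <- from_id
  for (nxt in path) {
    cm <- h$nodes[[at]]$column_maps[[nxt]]
    at_names <- names(h$nodes[[at]]$genome$seq)
    cur <- lapply(cur, function(v) {
      out_seq <- rep(NA_integer_, length(v$pos))
      out_pos <- rep(NA_integer_, length(v$pos))
      ok <- which(!is.na(v$pos))
      for (si in unique(v$seq[ok])) {
        sel <- ok[v$seq[ok] == si]
        m <- cm[[at_names[si]]]
        out_seq[sel] <- m$seq[v$pos[sel] + 1L]
        out_pos[sel] <- m$pos[v$pos[sel] + 1L]
      }
      list(seq = out_seq, pos = out_pos)
    })
    at <- nxt
  }
  cur
}

# path of node ids from a leaf up to the root (inclusive)
path_to_root <- function(tree, leaf) {
  po <- tree_postorder(tree)
  parent <- setNames(rep(NA_character_, nrow(po)), po$node_id)
  for (i in which(!po$is_leaf)) {
    parent[po$left[i]] <- po$node_id[i]
    parent[po$right[i]] <- po$node_id[i]
  }
  path <- leaf
  while (!is.na(parent[path[length(path)]]))
    path <- c(path, parent[[path[length(path)]]])
  path
}

#' Project a hierarchy into a reference-anchored pairwise alignment
#'
#' Composes column maps from both leaves through their lowest common
#' ancestor and emits maximal runs of co-mapped columns as two-row MAF
#' blocks, both rows on the + strand. Gap runs inside blocks are
#' reconstructed from positions present in only one leaf; junction
#' segments present in both leaves (material unrepresented at intermediate
#' ancestors) are re-aligned locally so every emitted row remains an exact
#' substring of its genome.
#'
#' @param h An [mga_hierarchy()].
#' @param ref_leaf,qry_leaf Leaf genome ids; `ref_leaf` becomes the first
#'   (reference) row.
#' @param params An [align_params()] object.
#' @return List of two-row [mga_block()] objects.
#' @export
project_pairwise <- function(h, ref_leaf, qry_leaf, params = align_params()) {
  stopifnot(inherits(h, "mga_hierarchy"))
  for (lf in unique(c(ref_leaf, qry_leaf)))
    if (is.null(h$nodes[[lf]]) || !is.null(h$nodes[[lf]]$children))
      abort(paste0("unknown or non-leaf node id: ", lf))
  pr <- path_to_root(h$tree, ref_leaf)
  pq <- path_to_root(h$tree, qry_leaf)
  if (ref_leaf == qry_leaf) {
    lca <- pr[2]  # the leaf's parent: identity projection over mapped positions
  } else {
    lca <- intersect(pr, pq)[1]
  }
  down_r <- rev(pr[seq_len(match(lca, pr))])[-1]  # lca -> ... -> ref_leaf
  down_q <- rev(pq[seq_len(match(lca, pq))])[-1]
  mr <- descend_map(h, lca, ref_leaf, down_r)
  mq <- descend_map(h, lca, qry_leaf, down_q)
  ref_g <- h$nodes[[ref_leaf]]$genome
  qry_g <- h$nodes[[qry_leaf]]$genome
  blocks <- list()
  for (nm in names(mr)) {
    vr <- mr[[nm]]; vq <- mq[[nm]]
    co <- which(!is.na(vr$pos) & !is.na(vq$pos))
    if (!length(co)) next
    key <- paste(vr$seq[co], vq$seq[co])
    for (kk in unique(key)) {
      sel <- co[key == kk]
      rs_name <- names(ref_g$seq)[vr$seq[sel[1]]]
      qs_name <- names(qry_g$seq)[vq$seq[sel[1]]]
      blocks <- c(blocks, pairs_to_blocks(vr$pos[sel] + 1L, vq$pos[sel] + 1L,
                                          ref_g, rs_name, qry_g, qs_name, params))
    }
  }
  blocks
}
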