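#' Estimate a guide tree from k-mer distances
#'
#' Pairwise distance = 1 - Jaccard similarity of canonical 21-mer sets,
#' clustered by UPGMA (average-linkage). Genomes are ordered
#' lexicographically by id before clustering so ties resolve
#' deterministically.
#'
#' @param genomes Named list of [mga_genome()] objects (names = genome ids),
#'   or an unnamed list (ids taken from the objects).
#' @param k K-mer length for the distance (canonical k-mers).
#' @return An `mga_tree` with UPGMA branch lengths.
#' @export
estimate_guide_tree <- function(genomes, k = 21L) {
  if (is.null(names(genomes)) || any(names(genomes) == ""))
    names(genomes) <- map_chr(genomes, "genome_id")
  if (length(genomes) < 2) abort("need at least 2 genomes to estimate a tree")
  ids <- sort(names(genomes))
  sets <- lapply(ids, function(id) {
    g <- genomes[[id]]
    sort(unique(unlist(lapply(unname(g$seq), cpp_kmer_set, k = as.integer(k)))))
  })
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ni <- length(sets[[i]]); nj <- length(sets[[j]])
    inter <- length(intersect(sets[[i]], sets[[j]]))
    jac <- if (ni + nj - inter > 0) inter / (ni + nj - inter) else 1
    D[i, j] <- D[j, i] <- 1 - jac
  }
  hc <- hclust(as.dist(D), method = "average")  # UPGMA
  phy <- ape::as.phylo(hc)
  read_newick(ape::write.tree(phy), expected_leaves = ids)
}

#' Hierarchy of aligned genomes
#'
#' The result of a progressive run: one node per guide-tree node, each
#' holding a (leaf or reconstructed ancestral) genome, its annotation, the
#' pairwise alignment of its two children (internal nodes), and per-child
#' column maps giving, for every ancestor position, its origin position in
#' the child (or `NA`). Column maps are strictly monotone where defined.
#'
#' @param nodes Named list of node records.
#' @param tree The guide `mga_tree`.
#' @return An object of class `mga_hierarchy`.
#' @export
mga_hierarchy <- function(nodes, tree) {
  structure(list(nodes = nodes, tree = tree), class = "mga_hierarchy")
}

#' @export
print.mga_hierarchy <- function(x, ...) {
  po <- tree_postorder(x$tree)
  cat(sprintf("<mga_hierarchy> %d nodes (%d leaves), root %s\n",
              nrow(po), sum(po$is_leaf), po$node_id[nrow(po)]))
  invisible(x)
}

# one column map: per ancestor sequence, integer vectors `seq` (index into
# the child's sequence names) and `pos` (0-based child position), NA where
# the ancestor position has no origin in that child
empty_map <- function(len) list(seq = rep(NA_integer_, len), pos = rep(NA_integer_, len))

#' Build an ancestral node from two child nodes
#'
#' The children are aligned with [align_genomes()] (left child as the
#' alignment reference). The ancestor sequence is assembled per left-child
#' sequence: the left child acts as the backbone (all its positions are
#' carried, including unaligned segments between collinear blocks, so no
#' backbone position becomes unreachable from the root); at match or
#' mismatch columns the ancestor takes the left child's base; right-child
#' insertions are retained when the gap run is at most
#' `params$max_keep_insert` bp and omitted otherwise. Right-child segments
#' not used by any block are appended as extra ancestor sequences named
#' `<node_id>_acc<N>`. Column maps record every ancestor position's origin
#' in each child.
#'
#' @param left,right Child node records (as stored in an [mga_hierarchy()]).
#' @param params An [align_params()] object.
#' @param node_id Identifier for the new ancestor node.
#' @return A node record: `node_id`, `genome`, `annotation`, `children`,
#'   `child_alignment`, `column_maps`.
#' @export
build_ancestor <- function(left, right, params = align_params(), node_id = "Anc") {
  blocks <- align_genomes(left$genome, left$annotation, right$genome, params)
  lseq_names <- names(left$genome$seq)
  rseq_names <- names(right$genome$seq)
  anc_seqs <- character(); anc_names <- character()
  maps_l <- list(); maps_r <- list()
  right_used <- lapply(rseq_names, function(nm) integer())
  names(right_used) <- rseq_names

  by_lseq <- split(blocks, map_chr(blocks, ~ .x$rows$seq[1]))
  for (ls in lseq_names) {
    lchars <- strsplit(left$genome$seq[[ls]], "", fixed = TRUE)[[1]]
    llen <- length(lchars)
    bl <- by_lseq[[ls]]
    if (!is.null(bl)) bl <- bl[order(map_int(bl, ~ .x$rows$start[1]))]
    pieces <- list(); pl <- list(); pr <- list()
    push <- function(chars, lmap_seq, lmap_pos, rmap_seq, rmap_pos) {
      k <- length(pieces) + 1L
      pieces[[k]] <<- chars
      pl[[k]] <<- list(seq = lmap_seq, pos = lmap_pos)
      pr[[k]] <<- list(seq = rmap_seq, pos = rmap_pos)
      invisible(NULL)
    }
    cursor <- 0L  # 0-based position on the left sequence
    lidx <- match(ls, lseq_names)
    if (!is.null(bl)) for (b in bl) {
      rstart <- b$rows$start[1]
      if (rstart > cursor) {  # unaligned left segment: carried as-is
        seg <- cursor:(rstart - 1L)
        push(lchars[seg + 1L], rep(lidx, length(seg)), seg,
             rep(NA_integer_, length(seg)), rep(NA_integer_, length(seg)))
      }
      qs <- b$rows$seq[2]
      qidx <- match(qs, rseq_names)
      cl <- column_positions(b$text[1], b$rows$start[1])
      cq <- column_positions(b$text[2], b$rows$start[2])
      right_used[[qs]] <- c(right_used[[qs]],
                            b$rows$start[2]:(b$rows$start[2] + b$rows$size[2] - 1L))
      keep <- cl$nongap
      ins <- !cl$nongap  # right-only columns
      if (any(ins)) {
        r <- rle(ins)
        run_id <- rep(seq_along(r$lengths), r$lengths)
        drop_run <- r$values & r$lengths > params$max_keep_insert
        keep <- keep | (ins & !drop_run[run_id])
      }
      cols <- which(keep)
      push(ifelse(cl$nongap[cols], cl$chars[cols], cq$chars[cols]),
           ifelse(cl$nongap[cols], lidx, NA_integer_), cl$pos[cols],
           ifelse(cq$nongap[cols], qidx, NA_integer_), cq$pos[cols])
      cursor <- b$rows$start[1] + b$rows$size[1]
    }
    if (cursor < llen) {
      seg <- cursor:(llen - 1L)
      push(lchars[seg + 1L], rep(lidx, length(seg)), seg,
           rep(NA_integer_, length(seg)), rep(NA_integer_, length(seg)))
    }
    anc_names <- c(anc_names, ls)
    anc_seqs <- c(anc_seqs, paste(unlist(pieces), collapse = ""))
    maps_l[[ls]] <- list(seq = unlist(lapply(pl, `[[`, "seq")),
                         pos = unlist(lapply(pl, `[[`, "pos")))
    maps_r[[ls]] <- list(seq = unlist(lapply(pr, `[[`, "seq")),
                         pos = unlist(lapply(pr, `[[`, "pos")))
  }

  # unused right-child material becomes extra ancestor sequences
  acc <- 0L
  for (rs in rseq_names) {
    rlen <- nchar(right$genome$seq[[rs]])
    used <- rep(FALSE, rlen)
    if (length(right_used[[rs]])) used[right_used[[rs]] + 1L] <- TRUE
    r <- rle(used)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ridx <- match(rs, rseq_names)
    for (i in seq_along(r$values)) {
      if (r$values[i]) next
      acc <- acc + 1L
      nm <- sprintf("%s_acc%d", node_id, acc)
      seg <- (starts[i] - 1L):(ends[i] - 1L)  # 0-based
      anc_names <- c(anc_names, nm)
      anc_seqs <- c(anc_seqs, substr(right$genome$seq[[rs]], starts[i], ends[i]))
      maps_l[[nm]] <- empty_map(length(seg))
      maps_r[[nm]] <- list(seq = rep(ridx, length(seg)), pos = seg)
    }
  }

  genome <- mga_genome(node_id, setNames(anc_seqs, anc_names))
  for (nm in names(maps_l)) attr(maps_l[[nm]], "child_names") <- lseq_names
  for (nm in names(maps_r)) attr(maps_r[[nm]], "child_names") <- rseq_names
  node <- list(node_id = node_id, genome = genome, annotation = NULL,
               children = c(left$node_id, right$node_id),
               child_alignment = blocks,
               column_maps = setNames(list(maps_l, maps_r),
                                      c(left$node_id, right$node_id)))
  node$annotation <- lift_annotation(node, left$annotation, right$annotation)
  node
}

#' Lift child CDS annotation onto an ancestor
#'
#' Each child CDS interval is projected through that child's column map;
#' projections covering at least 80% of the CDS length are kept, and
#' overlapping projections from the two children are merged into one
#' feature spanning their union. The merged CDS set is what makes the
#' ancestor usable as the anchor source of the next progressive iteration.
#'
#' @param node A node record with populated `column_maps`.
#' @param left_ann,right_ann Child [mga_features()] annotations.
#' @param min_cover Minimum projected fraction of the CDS length.
#' @return An [mga_features()] table on the ancestor genome.
#' @export
lift_annotation <- function(node, left_ann, right_ann, min_cover = 0.8) {
  proj <- list()
  for (ci in 1:2) {
    child_id <- node$children[ci]
    ann <- if (ci == 1) left_ann else right_ann
    if (is.null(ann) || !nrow(ann)) next
    cmap <- node$column_maps[[child_id]]
    cds <- ann[ann$type == "CDS", ]
    if (!nrow(cds)) next
    for (as_name in names(cmap)) {
      m <- cmap[[as_name]]
      if (all(is.na(m$pos))) next
      child_names <- attr(m, "child_names")
      for (sidx in unique(m$seq[!is.na(m$seq)])) {
        idxs <- which(!is.na(m$pos) & !is.na(m$seq) & m$seq == sidx)
        pv <- m$pos[idxs]
        here <- cds[cds$seq == child_names[sidx], ]
        for (fi in seq_len(nrow(here))) {
          hit <- idxs[pv >= here$start[fi] & pv < here$end[fi]]
          if (!length(hit)) next
          cov <- length(hit) / (here$end[fi] - here$start[fi])
          if (cov < min_cover) next
          proj[[length(proj) + 1L]] <- tibble(
            seq = as_name, start = min(hit) - 1L, end = max(hit),
            strand = here$strand[fi], child = child_id)
        }
      }
    }
  }
  if (!length(proj))
    return(mga_features(tibble(seq = character(), start = integer(), end = integer(),
                               strand = character(), type = character(),
                               feature_id = character(), parent_id = character())))
  pr <- bind_rows(proj)
  merged <- lapply(split(pr, pr$seq), function(d) {
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    strands <- map_chr(as.list(S4Vectors::mcols(red)$revmap),
                       ~ d$strand[.x[order(match(d$child[.x], d$child))[1]]])
    tibble(seq = d$seq[1], start = IRanges::start(red) - 1L, end = IRanges::end(red),
           strand = strands)
  })
  mg <- arrange(bind_rows(merged), .data$seq, .data$start)
  gid <- sprintf("%s_gene%d", node$node_id, seq_len(nrow(mg)))
  feat <- bind_rows(
    mutate(mg, type = "gene", feature_id = gid, parent_id = NA_character_),
    mutate(mg, type = "mRNA", feature_id = paste0(gid, ".1"), parent_id = gid),
    mutate(mg, type = "CDS", feature_id = paste0(gid, ".1.cds"),
           parent_id = paste0(gid, ".1")))
  mga_features(feat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full progressive alignment
#'
#' Post-order traversal of the guide tree; each internal node is built by
#' [build_ancestor()] (aligning its two children and reconstructing an
#' ancestral genome) and annotated by [lift_annotation()]. The run is
#' deterministic given inputs and parameters.
#'
#' @param genomes Named list of leaf [mga_genome()] objects.
#' @param annotations Named list of leaf [mga_features()] tables (same
#'   names as `genomes`).
#' @param tree Guide `mga_tree` whose leaves equal the genome ids.
#' @param params An [align_params()] object.
#' @return An [mga_hierarchy()].
#' @export
progressive_align <- function(genomes, annotations, tree, params = align_params()) {
  if (is.null(names(genomes)) || any(names(genomes) == ""))
    names(genomes) <- map_chr(genomes, "genome_id")
  lv <- tree_leaves(tree)
  if (!setequal(lv, names(genomes)))
    abort(sprintf("tree leaves [%s] do not match genomes [%s]",
                  paste(sort(lv), collapse = ", "),
                  paste(sort(names(genomes)), collapse = ", ")))
  po <- tree_postorder(tree)
  nodes <- list()
  log <- character()
  for (i in seq_len(nrow(po))) {
    nid <- po$node_id[i]
    if (po$is_leaf[i]) {
      ann <- annotations[[nid]]
      if (is.null(ann))
        ann <- mga_features(tibble(seq = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   type = character(), feature_id = character(),
                                   parent_id = character()))
      nodes[[nid]] <- list(node_id = nid, genome = genomes[[nid]],
                           annotation = ann, children = NULL,
                           child_alignment = NULL, column_maps = NULL)
    } else {
      left <- nodes[[po$left[i]]]; right <- nodes[[po$right[i]]]
      node <- tryCatch(
        build_ancestor(left, right, params, node_id = nid),
        error = function(e) abort(sprintf("while building node %s: %s", nid,
                                          conditionMessage(e))))
      nodes[[nid]] <- node
      log <- c(log, sprintf("built %s from (%s, %s)", nid, po$left[i], po$right[i]))
    }
  }
  h <- mga_hierarchy(nodes, tree)
  attr(h, "log") <- log
  h
}
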