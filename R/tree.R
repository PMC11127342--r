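#' Guide tree
#'
#' A rooted guide tree ordering the progressive merge of genomes. Leaves
#' are labelled by genome id; internal nodes receive ids `Anc0..AncK` in
#' post-order. Multifurcations are resolved into binary nodes
#' deterministically (left-to-right ladderization), so every internal node
#' has exactly two children.
#'
#' The object is a recursive list: `list(id, children, length)` where
#' `children` is a list of subtrees (empty at leaves) and `length` is the
#' branch length to the parent (`NA` if absent).
#'
#' @name mga_tree
NULL

new_tree_node <- function(id, children = list(), length = NA_real_) {
  structure(list(id = id, children = children, length = length), class = "mga_tree")
}

#' Leaf labels of a guide tree
#' @param tree An `mga_tree`.
#' @return Character vector of leaf labels, left to right.
#' @export
tree_leaves <- function(tree) {
  if (!length(tree$children)) return(tree$id)
  unlist(lapply(tree$children, tree_leaves))
}

#' Flatten a guide tree into a traversal table
#'
#' @param tree An `mga_tree`.
#' @return Tibble in post-order with columns `node_id`, `left`, `right`
#'   (`NA` at leaves), `length`, `is_leaf`.
#' @export
tree_postorder <- function(tree) {
  acc <- list()
  walk <- function(node) {
    kids <- map_chr(node$children, "id")
    for (ch in node$children) walk(ch)
    acc[[length(acc) + 1L]] <<- tibble(
      node_id = node$id,
      left = if (length(kids)) kids[1] else NA_character_,
      right = if (length(kids)) kids[2] else NA_character_,
      length = node$length,
      is_leaf = !length(kids))
    invisible(NULL)
  }
  walk(tree)
  bind_rows(acc)
}

# resolve multifurcations left-to-right: (c1,c2,c3,...) -> (((c1,c2),c3),...)
resolve_multifurcations <- function(node) {
  if (!length(node$children)) return(node)
  node$children <- lapply(node$children, resolve_multifurcations)
  while (length(node$children) > 2) {
    merged <- new_tree_node("", children = node$children[1:2], length = 0)
    node$children <- c(list(merged), node$children[-(1:2)])
  }
  node
}

# assign Anc0..AncK to internal nodes in post-order
label_ancestors <- function(node) {
  counter <- 0L
  walk <- function(nd) {
    nd$children <- lapply(nd$children, walk)
    if (length(nd$children)) {
      nd$id <- paste0("Anc", counter)
      counter <<- counter + 1L
    }
    nd
  }
  walk(node)
}

phylo_to_tree <- function(phy) {
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  build <- function(node) {
    if (node <= n_tip) return(new_tree_node(phy$tip.label[node]))
    rows <- kids[[as.character(node)]]
    ch <- lapply(rows, function(r) {
      sub <- build(phy$edge[r, 2])
      sub$length <- if (!is.null(phy$edge.length)) phy$edge.length[r] else NA_real_
      sub
    })
    new_tree_node("", children = ch)
  }
  build(root)
}

#' Read a rooted guide tree from Newick
#'
#' The leaf set must equal `expected_leaves`; multifurcations are resolved
#' left-to-right into binary nodes and internal nodes are labelled
#' `Anc0..AncK` in post-order.
#'
#' @param path Path to a Newick file (or a literal Newick string).
#' @param expected_leaves Character vector of genome ids the tree must
#'   cover exactly.
#' @return An `mga_tree`.
#' @export
read_newick <- function(path, expected_leaves) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "") else path
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) abort("could not parse Newick input")
  tree <- phylo_to_tree(phy)
  lv <- tree_leaves(tree)
  if (anyDuplicated(lv))
    abort(paste0("duplicate leaf labels: ", paste(unique(lv[duplicated(lv)]), collapse = ", ")))
  missing <- setdiff(expected_leaves, lv)
  extra <- setdiff(lv, expected_leaves)
  if (length(missing) || length(extra))
    abort(sprintf("leaf set mismatch; missing: [%s], extra: [%s]",
                  paste(missing, collapse = ", "), paste(extra, collapse = ", ")))
  label_ancestors(resolve_multifurcations(tree))
}

#' Write a guide tree as a Newick string
#' @param tree An `mga_tree`.
#' @param path Optional output path; if `NULL` the string is returned.
#' @param digits Digits for branch lengths.
#' @return The Newick string (invisibly if written to a file).
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  fmt <- function(node) {
    core <- if (length(node$children)) {
      paste0("(", paste(map_chr(node$children, fmt), collapse = ","), ")", node$id)
    } else node$id
    if (!is.na(node$length)) paste0(core, ":", format(node$length, digits = digits)) else core
  }
  s <- paste0(fmt(tree), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
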