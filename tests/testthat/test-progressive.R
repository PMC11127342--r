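test_that("k-mer distance tree recovers the obvious topology", {
  fx <- toy_annotated_genome(n_genes = 4)
  gA <- fx$genome; gA$genome_id <- "A"
  gB <- mutate_genome(gA, "B", snv_at = seq(50L, 2500L, by = 97L))    # ~1%
  gC <- mutate_genome(gA, "C", snv_at = seq(30L, 2700L, by = 11L))    # ~10%
  tr <- estimate_guide_tree(list(A = gA, B = gB, C = gC))
  po <- tree_postorder(tr)
  first <- po[!po$is_leaf, ][1, ]
  expect_setequal(c(first$left, first$right), c("A", "B"))

  # identical genomes: distance zero; same input gives the same Newick
  expect_identical(write_newick(estimate_guide_tree(list(A = gA, B = gB, C = gC))),
                   write_newick(tr))
  expect_error(estimate_guide_tree(list(A = gA)), "at least 2")
})

test_that("identical children produce an ancestor equal to the left child", {
  fx <- toy_annotated_genome(n_genes = 4)
  mk <- function(id) {
    g <- fx$genome; g$genome_id <- id
    list(node_id = id, genome = g, annotation = fx$annotation, children = NULL)
  }
  anc <- build_ancestor(mk("L"), mk("R"), align_params(), node_id = "Anc0")
  expect_identical(anc$genome$seq[["chr1"]], fx$genome$seq[["chr1"]])
  m <- anc$column_maps[["L"]][["chr1"]]
  expect_identical(m$pos, 0:(nchar(fx$genome$seq[[1]]) - 1L))
  m2 <- anc$column_maps[["R"]][["chr1"]]
  expect_identical(m2$pos, m$pos)
  # lifted annotation covers the CDS set
  expect_equal(sum(anc$annotation$type == "CDS"), 4)
})

test_that("a right-child insertion is kept in the ancestor within the cap", {
  fx <- toy_annotated_genome(n_genes = 4, gene_len = 300, gap = 500)
  mkL <- function() {
    g <- fx$genome; g$genome_id <- "L"
    list(node_id = "L", genome = g, annotation = fx$annotation, children = NULL)
  }
  ins <- strrep("ACGTT", 20)  # 100 bp insertion mid-gap
  gR <- mutate_genome(fx$genome, "R", ins_at = 900L, ins_seq = ins)
  right <- list(node_id = "R", genome = gR, annotation = NULL, children = NULL)
  anc <- build_ancestor(mkL(), right, align_params(), node_id = "AncX")
  expect_equal(nchar(anc$genome$seq[["chr1"]]),
               nchar(fx$genome$seq[["chr1"]]) + 100L)
  mL <- anc$column_maps[["L"]][["chr1"]]
  expect_equal(sum(is.na(mL$pos)), 100L)  # left map skips the insertion

  # beyond the cap the insertion is dropped from the ancestor
  p2 <- align_params(max_keep_insert = 50L)
  anc2 <- build_ancestor(mkL(), right, p2, node_id = "AncY")
  expect_equal(nchar(anc2$genome$seq[["chr1"]]), nchar(fx$genome$seq[[1]]))
})

test_that("progressive run over identical leaves is an identity hierarchy", {
  fx <- toy_annotated_genome(n_genes = 4)
  ids <- c("A", "B", "C", "D")
  genomes <- lapply(ids, function(id) { g <- fx$genome; g$genome_id <- id; g })
  names(genomes) <- ids
  anns <- setNames(rep(list(fx$annotation), 4), ids)
  tree <- read_newick("((A,B),(C,D));", expected_leaves = ids)
  h <- progressive_align(genomes, anns, tree, align_params())
  expect_length(h$nodes, 7)
  expect_equal(length(attr(h, "log")), 3)  # three ancestors, post-order
  root <- h$nodes[[tree_postorder(h$tree)$node_id[7]]]
  expect_identical(root$genome$seq[["chr1"]], fx$genome$seq[["chr1"]])
  # projections are identity and call no variants
  for (lf in c("B", "C")) {
    vs <- extract_variants(project_pairwise(h, "A", lf), genomes$A, lf)
    expect_equal(nrow(vs), 0)
  }
})

test_that("two-leaf projection equals the direct child alignment column set", {
  fx <- toy_annotated_genome(n_genes = 4)
  gA <- fx$genome; gA$genome_id <- "A"
  gB <- mutate_genome(gA, "B", snv_at = c(400L, 1100L), del_at = 1500L, del_len = 60L)
  tree <- read_newick("(A,B);", expected_leaves = c("A", "B"))
  h <- progressive_align(list(A = gA, B = gB),
                         list(A = fx$annotation, B = NULL), tree, align_params())
  direct <- h$nodes[[tree_postorder(h$tree)$node_id[3]]]$child_alignment
  proj <- project_pairwise(h, "A", "B")
  colset <- function(blocks) {
    out <- character(0)
    for (b in blocks) {
      cr <- column_positions(b$text[1], b$rows$start[1])
      cq <- column_positions(b$text[2], b$rows$start[2])
      both <- cr$nongap & cq$nongap
      out <- c(out, paste(cr$pos[both], cq$pos[both]))
    }
    sort(out)
  }
  expect_identical(colset(proj), colset(direct))
})

test_that("projection is monotone and never reuses a reference position", {
  fx <- toy_annotated_genome(n_genes = 5)
  gA <- fx$genome; gA$genome_id <- "A"
  gB <- mutate_genome(gA, "B", snv_at = seq(100L, 3000L, 211L))
  gC <- mutate_genome(gA, "C", snv_at = seq(150L, 3000L, 179L))
  tree <- read_newick("((A,B),C);", expected_leaves = c("A", "B", "C"))
  h <- progressive_align(list(A = gA, B = gB, C = gC),
                         list(A = fx$annotation, B = NULL, C = NULL),
                         tree, align_params())
  proj <- project_pairwise(h, "A", "C")
  seen <- integer(0)
  for (b in proj) {
    cr <- column_positions(b$text[1], b$rows$start[1])
    cq <- column_positions(b$text[2], b$rows$start[2])
    expect_true(all(diff(cr$pos[cr$nongap]) > 0))
    expect_true(all(diff(cq$pos[cq$nongap]) > 0))
    seen <- c(seen, cr$pos[cr$nongap])
  }
  expect_false(any(duplicated(seen)))
})

test_that("ancestor length is bounded by its children", {
  fx <- toy_annotated_genome(n_genes = 4)
  gA <- fx$genome; gA$genome_id <- "A"
  gB <- mutate_genome(gA, "B", ins_at = 900L, ins_seq = strrep("TTAGC", 30))
  tree <- read_newick("(A,B);", expected_leaves = c("A", "B"))
  h <- progressive_align(list(A = gA, B = gB),
                         list(A = fx$annotation, B = NULL), tree, align_params())
  anc <- h$nodes[[tree_postorder(h$tree)$node_id[3]]]
  tot <- sum(nchar(anc$genome$seq))
  expect_lte(tot, sum(nchar(gA$seq)) + sum(nchar(gB$seq)))
  expect_gte(tot, sum(nchar(gA$seq)))
})
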