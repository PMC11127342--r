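test_that("anchor queries take the longest mRNA, spliced and oriented", {
  g <- mga_genome("t", c(chr1 = paste0(strrep("T", 10),
                                       "ATGAAACCCGGGTAA",      # gene1 +
                                       strrep("C", 10))))
  ft <- mga_features(tibble::tibble(
    seq = "chr1",
    start = c(10L, 10L, 10L, 10L, 10L, 10L, 19L),
    end = c(25L, 25L, 25L, 25L, 19L, 25L, 25L),
    strand = "+",
    type = c("gene", "mRNA", "CDS", "mRNA", "CDS", "mRNA", "CDS"),
    feature_id = c("g1", "m1", "c1", "m2", "c2", "m3", "c3"),
    parent_id = c(NA, "g1", "m1", "g1", "m2", "g1", "m3")), genome = g)
  q <- extract_anchor_queries(g, ft)
  expect_equal(nrow(q), 1)             # one query per gene
  expect_equal(q$feature_id, "m1")     # longest splice form wins
  expect_equal(q$query, "ATGAAACCCGGGTAA")

  # minus strand: reverse complement of the genomic slice
  ftm <- mga_features(tibble::tibble(
    seq = "chr1", start = c(10L, 10L, 10L), end = c(25L, 25L, 25L),
    strand = "-", type = c("gene", "mRNA", "CDS"),
    feature_id = c("g1", "m1", "c1"), parent_id = c(NA, "g1", "m1")),
    genome = g)
  qm <- extract_anchor_queries(g, ftm)
  expect_equal(qm$query, revcomp("ATGAAACCCGGGTAA"))
  expect_equal(c(qm$ref_start, qm$ref_end), c(10L, 25L))
})

test_that("identical genomes give identity anchors at identical coordinates", {
  fx <- toy_annotated_genome(n_genes = 5)
  anc <- match_anchors(extract_anchor_queries(fx$genome, fx$annotation),
                       fx$genome, align_params())
  expect_equal(nrow(anc), 5)
  expect_true(all(anc$identity == 1))
  expect_identical(anc$qry_start, anc$ref_start)
  expect_identical(anc$qry_end, anc$ref_end)
  expect_true(all(anc$strand == "+"))
})

test_that("a CDS with a couple of mismatches places with matching identity", {
  fx <- toy_annotated_genome(n_genes = 3, gene_len = 300)
  cds <- fx$annotation[fx$annotation$type == "CDS", ][1, ]
  qry <- mutate_genome(fx$genome, "q", snv_at = c(cds$start + 100L, cds$start + 200L))
  anc <- match_anchors(extract_anchor_queries(fx$genome, fx$annotation),
                       qry, align_params())
  a1 <- anc[anc$ref_start == cds$start, ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$identity, (300 - 2) / 300, tolerance = 1e-9)
})

test_that("a CDS copied to many loci is dropped as repetitive-ambiguous", {
  fx <- toy_annotated_genome(n_genes = 2, gene_len = 300, gap = 300)
  cds <- fx$annotation[fx$annotation$type == "CDS", ][1, ]
  gene_seq <- substr(fx$genome$seq[[1]], cds$start + 1, cds$end)
  filler <- substr(fx$genome$seq[[1]], 1, 200)
  qry <- mga_genome("q", c(chr1 = paste0(
    fx$genome$seq[[1]], paste(rep(paste0(filler, gene_seq), 5), collapse = ""))))
  anc <- match_anchors(extract_anchor_queries(fx$genome, fx$annotation),
                       qry, align_params())
  expect_false(cds$start %in% anc$ref_start)  # ambiguous CDS gone
  expect_true(nrow(anc) >= 1)                 # the other gene still anchors
})

test_that("minus-strand placement is recorded with relative strand", {
  fx <- toy_annotated_genome(n_genes = 1, gene_len = 300, gap = 200)
  qry <- mga_genome("q", c(chr1 = revcomp(fx$genome$seq[[1]])))
  anc <- match_anchors(extract_anchor_queries(fx$genome, fx$annotation),
                       qry, align_params())
  expect_equal(nrow(anc), 1)
  expect_equal(anc$strand, "-")
})

test_that("collinear chaining keeps monotone anchors and drops strays", {
  p <- align_params()
  mk <- function(rs, qs, len = 100) tibble::tibble(
    feature_id = paste0("a", rs), ref_seq = "chr1",
    ref_start = rs, ref_end = rs + len,
    qry_seq = "chr1", qry_start = qs, qry_end = qs + len,
    strand = "+", identity = 1)
  a <- dplyr::bind_rows(mk(100, 100), mk(300, 310), mk(500, 520))
  ch <- chain_collinear(a, p)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$anchors), 3)

  # an out-of-order anchor is excluded from the chain
  b <- dplyr::bind_rows(mk(100, 100), mk(300, 50), mk(500, 520))
  ch2 <- chain_collinear(b, p)
  expect_length(ch2, 1)
  expect_equal(ch2[[1]]$anchors$ref_start, c(100, 500))

  expect_length(chain_collinear(a[0, ], p), 0)
})

test_that("chaining DP matches exhaustive enumeration on small anchor sets", {
  p <- align_params()
  score_chain <- function(d, idx) {
    # score a candidate chain the way the DP defines it
    sc <- sum(d$identity[idx] * (d$ref_end[idx] - d$ref_start[idx] +
                                   d$qry_end[idx] - d$qry_start[idx]) / 2)
    if (length(idx) > 1) for (k in 2:length(idx)) {
      i <- idx[k - 1]; j <- idx[k]
      rg <- d$ref_start[j] - d$ref_end[i]
      qg <- d$qry_start[j] - d$qry_end[i]
      if (rg < 0 || qg < 0) return(-Inf)
      sc <- sc - (p$E2 * abs(rg - qg) + 1)
    }
    sc
  }
  n_checked <- 0L
  withr::with_seed(21, {
    for (trial in 1:15) {
      n <- sample(3:7, 1)
      ref_start <- sort(sample.int(2000, n)) * 10L
      # mostly collinear placements with jitter, some shuffled away
      qry_start <- ref_start + sample(-300:300, n, replace = TRUE)
      shuffle <- runif(n) < 0.25
      qry_start[shuffle] <- sample.int(20000, sum(shuffle))
      d <- tibble::tibble(
        feature_id = paste0("a", 1:n), ref_seq = "chr1",
        ref_start = ref_start, qry_seq = "chr1",
        qry_start = as.integer(qry_start),
        strand = "+", identity = 1)
      d$ref_end <- d$ref_start + 50L
      d$qry_end <- d$qry_start + 50L
      # exhaustive best chain over all ordered subsets (incl. singletons,
      # which the DP considers but never emits)
      idxs <- seq_len(n)
      best <- -Inf; best_m <- 0L
      for (m in seq_len(n)) for (cc in utils::combn(idxs, m, simplify = FALSE)) {
        sc <- score_chain(d, cc)
        if (sc > best) { best <- sc; best_m <- m }
      }
      ch <- chain_collinear(d, p)
      got <- if (length(ch)) max(vapply(ch, `[[`, numeric(1), "chain_score")) else -Inf
      # when the exhaustive optimum uses >= 2 anchors and is non-negative,
      # the DP's top emitted chain must reach it
      if (best_m >= 2 && best >= 0) {
        n_checked <- n_checked + 1L
        expect_equal(got, best, info = paste("trial", trial))
      }
    }
  })
  expect_gte(n_checked, 5)
})
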