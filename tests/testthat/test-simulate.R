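small_cfg <- function(seed = 3, ...) {
  sim_config(seed = seed, tree = "(A:0.5,B:0.5);", genome_length = 30000L,
             n_genes = 12L, ...)
}

test_that("root generation honours the configured gene and repeat content", {
  cfg <- small_cfg()
  root <- generate_root(cfg)
  expect_equal(nchar(root$genome$seq[["chr1"]]), 30000L)
  expect_equal(sum(root$annotation$type == "gene"), 12L)
  cds <- root$annotation[root$annotation$type == "CDS", ]
  expect_true(all((cds$end - cds$start) %% 3 == 0))
  for (i in seq_len(nrow(cds))) {
    gseq <- substr(root$genome$seq[[1]], cds$start[i] + 1, cds$end[i])
    if (cds$strand[i] == "-") gseq <- revcomp(gseq)
    expect_equal(substr(gseq, 1, 3), "ATG")
    expect_true(substr(gseq, nchar(gseq) - 2, nchar(gseq)) %in% c("TAA", "TAG", "TGA"))
  }
  # repeat fraction tracked within discrete-placement tolerance
  cfg2 <- sim_config(seed = 5, tree = "(A:0.5,B:0.5);", genome_length = 100000L,
                     n_genes = 10L, repeat_fraction = 0.5)
  root2 <- generate_root(cfg2)
  expect_lt(abs(region_length(root2$repeats) - 50000L), 2000L)

  # degenerate config: no genes, no repeats
  cfg0 <- sim_config(seed = 1, tree = "(A:0.5,B:0.5);", genome_length = 5000L,
                     n_genes = 0L, repeat_fraction = 0)
  root0 <- generate_root(cfg0)
  expect_equal(nrow(root0$annotation), 0L)
  expect_equal(nrow(root0$repeats), 0L)

  expect_error(generate_root(sim_config(seed = 1, tree = "(A:1,B:1);",
                                        genome_length = 1000L, n_genes = 50L)),
               "cannot fit")
})

test_that("root generation is byte-deterministic under the seed", {
  a <- generate_root(small_cfg())
  b <- generate_root(small_cfg())
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_identical(as.data.frame(a$repeats), as.data.frame(b$repeats))
})

test_that("zero rates leave the child identical to the parent", {
  cfg <- small_cfg(snv_rate = 0, short_indel_rate = 0, long_indel_rate = 0)
  root <- generate_root(cfg)
  set.seed(1)
  ev <- evolve_branch(root, 0.5, cfg)
  expect_identical(ev$genome$seq, root$genome$seq)
  expect_equal(nrow(ev$edits), 0L)
  expect_identical(ev$parent_map[["chr1"]], seq_len(30000L))
})

test_that("event counts are Poisson around rate x branch x length", {
  cfg <- small_cfg(snv_rate = 0.01, short_indel_rate = 0, long_indel_rate = 0)
  root <- generate_root(cfg)
  # expected 100 SNVs at branch (1/3); Poisson(100) lies in [60, 140]
  # with probability > 99.9%, so 20 independent draws all land there
  set.seed(42)
  for (i in 1:20) {
    ev <- evolve_branch(root, 100 / (0.01 * 30000), cfg)
    n <- sum(ev$edits$type == "SNV")
    expect_true(n >= 60 && n <= 140, info = paste("draw", i, "got", n))
  }
})

test_that("long INDEL events respect the configured length bounds", {
  cfg <- small_cfg(snv_rate = 0, short_indel_rate = 0, long_indel_rate = 5e-4,
                   long_indel_max = 500L)
  root <- generate_root(cfg)
  set.seed(7)
  ev <- evolve_branch(root, 0.5, cfg)
  lens <- ev$edits$len[ev$edits$type %in% c("INS", "DEL")]
  expect_gt(length(lens), 0)
  expect_true(all(lens >= 51 & lens <= 500))
})

test_that("a star-like zero-rate tree gives identical leaves and empty truth", {
  cfg <- sim_config(seed = 9, tree = "((A:0,B:0):0,(C:0,D:0):0);",
                    genome_length = 20000L, n_genes = 8L,
                    snv_rate = 0, short_indel_rate = 0, long_indel_rate = 0)
  sim <- simulate_genomes(cfg)
  expect_identical(sim$genomes$A$seq, sim$genomes$D$seq)
  for (tr in sim$truth) expect_equal(nrow(tr$variants), 0L)
})

test_that("simulation is deterministic under the seed", {
  s1 <- simulate_genomes(small_cfg(seed = 17))
  s2 <- simulate_genomes(small_cfg(seed = 17))
  expect_identical(s1$genomes$B$seq, s2$genomes$B$seq)
  expect_identical(as.data.frame(s1$truth$B$variants),
                   as.data.frame(s2$truth$B$variants))
})

test_that("truth variants rebuild each leaf over the syntenic spans", {
  sim <- simulate_genomes(small_cfg(seed = 29))
  ref <- sim$genomes[[sim$reference_leaf]]
  for (lf in names(sim$truth)) {
    tr <- sim$truth[[lf]]
    rec <- apply_variants(ref, tr$variants)
    org <- rec$origin[["chr1"]]
    rc <- strsplit(rec$seq[["chr1"]], "", fixed = TRUE)[[1]]
    qseq <- sim$genomes[[lf]]$seq[["chr1"]]
    # spans are recorded with matching query intervals via the truth blocks;
    # reconstruct each span and compare to the aligned query segment
    expect_gt(nrow(tr$spans), 0)
    total <- sum(tr$spans$end - tr$spans$start)
    expect_gt(total / nchar(ref$seq[["chr1"]]), 0.9)
    for (i in seq_len(nrow(tr$spans))) {
      s <- tr$spans$start[i] + 1L; e <- tr$spans$end[i]
      idx <- which(!is.na(org) & org >= s & org <= e)
      seg <- paste(rc[min(idx):max(idx)], collapse = "")
      expect_true(grepl(seg, qseq, fixed = TRUE) || seg == qseq,
                  info = paste(lf, "span", i))
    }
  }
})

test_that("an engineered deletion appears in the truth set at full length", {
  # two-leaf tree where only the query branch mutates, with exactly one
  # event class enabled at a rate giving a handful of long deletions
  cfg <- sim_config(seed = 41, tree = "(A:0,B:1);", genome_length = 30000L,
                    n_genes = 10L, snv_rate = 0, short_indel_rate = 0,
                    long_indel_rate = 1e-4, long_indel_max = 200L)
  sim <- simulate_genomes(cfg)
  tv <- tibble::as_tibble(sim$truth$B$variants)
  lens <- abs(nchar(tv$ref) - nchar(tv$alt))
  expect_gt(nrow(tv), 0)
  expect_true(all(tv$vclass %in% c("INS", "DEL")))
  expect_true(all(lens >= 51 | lens %% 3 == 0))  # CDS-bias may round lengths
})
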