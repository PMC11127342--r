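test_that("position match and aligned bp follow the coverage definitions", {
  ref <- mga_genome("ref", c(chr1 = "ACGTACGTAC"))
  wg <- whole_genome_regions(ref)
  b <- mk_block("ACGTACGTAC", "ACGTA--TAC", rsrc = 10L, qsrc = 8L)
  m <- region_metrics(list(b), wg, ref)
  expect_equal(m$position_match_bp, 8L)
  expect_equal(m$aligned_bp, 8L)

  # two blocks over the same positions: multiplicity counts in aligned_bp
  m2 <- region_metrics(list(b, b), wg, ref)
  expect_equal(m2$position_match_bp, 8L)
  expect_equal(m2$aligned_bp, 16L)

  # region disjoint from all blocks
  far <- region_set(tibble::tibble(seq = "chr1", start = 5L, end = 7L), "gap-zone")
  m3 <- region_metrics(list(b), far, ref)
  expect_equal(c(m3$position_match_bp, m3$aligned_bp), c(0L, 0L))

  bad <- region_set(tibble::tibble(seq = "chrX", start = 0L, end = 5L), "x")
  expect_error(region_metrics(list(b), bad, ref), "absent")
})

test_that("position match is additive over a partition of the genome", {
  fx <- toy_annotated_genome(n_genes = 4)
  qry <- mutate_genome(fx$genome, "q", snv_at = c(300L, 900L), del_at = 1200L,
                       del_len = 80L)
  blocks <- align_genomes(fx$genome, fx$annotation, qry, align_params())
  L <- nchar(fx$genome$seq[[1]])
  cut <- floor(L / 3)
  parts <- list(
    region_set(tibble::tibble(seq = "chr1", start = 0L, end = cut), "p1"),
    region_set(tibble::tibble(seq = "chr1", start = cut, end = 2L * cut), "p2"),
    region_set(tibble::tibble(seq = "chr1", start = 2L * cut, end = L), "p3"))
  whole <- region_metrics(blocks, whole_genome_regions(fx$genome), fx$genome)
  split3 <- region_metrics(blocks, parts, fx$genome)
  expect_equal(sum(split3$position_match_bp), whole$position_match_bp)
  expect_equal(sum(split3$aligned_bp), whole$aligned_bp)
})

test_that("indel spectrum contrasts mod-3 fractions inside and outside CDS", {
  cds <- region_set(tibble::tibble(seq = "chr1", start = 0L, end = 100L), "CDS")
  mkdel <- function(pos, len) tibble::tibble(
    chrom = "chr1", pos = pos,
    ref = paste0("A", strrep("C", len)), alt = "A", vclass = "DEL")
  # CDS lengths 3,6,3,4 ; non-CDS lengths 1,2,3,5
  d <- dplyr::bind_rows(mkdel(10, 3), mkdel(20, 6), mkdel(30, 3), mkdel(40, 4),
                        mkdel(200, 1), mkdel(210, 2), mkdel(220, 3), mkdel(230, 5))
  vs <- mga_variants(d, sample = "s", reference_id = "ref")
  sp <- indel_spectrum(vs, cds)
  expect_equal(sp$cds_mod3_fraction, 0.75)
  expect_equal(sp$noncds_mod3_fraction, 0.25)
  expect_equal(sp$ratio, 3.0)
  expect_equal(sp$n_cds, 4L)

  # no CDS INDELs: ratio undefined
  sp2 <- indel_spectrum(mga_variants(mkdel(200, 4), sample = "s", reference_id = "r"),
                        cds)
  expect_true(is.na(sp2$ratio))

  # all multiples of three in both classes: ratio 1, no signal
  d3 <- dplyr::bind_rows(mkdel(10, 3), mkdel(20, 6), mkdel(200, 3), mkdel(210, 9))
  sp3 <- indel_spectrum(mga_variants(d3, sample = "s", reference_id = "r"), cds)
  expect_equal(sp3$ratio, 1.0)
})

test_that("multi-allelic counting matches the hand-constructed configurations", {
  ref <- mga_genome("ref", c(chr1 = strrep("ACGT", 25)))
  mkset <- function(df, s) mga_variants(df, sample = s, reference_id = "ref")
  del_at <- function(pos, len) {
    refal <- substr(ref$seq[[1]], pos, pos + len)
    tibble::tibble(chrom = "chr1", pos = pos, ref = refal,
                   alt = substr(refal, 1, 1), vclass = "DEL")
  }
  snv_at <- function(pos, alt) {
    base <- substr(ref$seq[[1]], pos, pos)
    tibble::tibble(chrom = "chr1", pos = pos, ref = base, alt = alt,
                   vclass = "SNV")
  }
  ins_at <- function(pos, ins) {
    base <- substr(ref$seq[[1]], pos, pos)
    tibble::tibble(chrom = "chr1", pos = pos, ref = base,
                   alt = paste0(base, ins), vclass = "INS")
  }

  # deletion + SNV inside it: the deletion length is counted
  r1 <- count_multiallelic(list(mkset(del_at(10, 10), "s1"),
                                mkset(snv_at(12, "G"), "s2")), ref)
  expect_equal(r1$affected_bp, 10L)

  # two different insertion alleles at one site: one base pair
  r2 <- count_multiallelic(list(mkset(ins_at(30, "AA"), "s1"),
                                mkset(ins_at(30, "CC"), "s2")), ref)
  expect_equal(r2$affected_bp, 1L)

  # two different SNV alleles at one site: one base pair
  r3 <- count_multiallelic(list(mkset(snv_at(5, "C"), "s1"),
                                mkset(snv_at(5, "T"), "s2")), ref)
  expect_equal(r3$affected_bp, 1L)

  # overlapping deletions [10,20) and [15,25): footprint union 15 bp
  r4 <- count_multiallelic(list(mkset(del_at(9, 10), "s1"),
                                mkset(del_at(14, 10), "s2")), ref)
  expect_equal(r4$affected_bp, 15L)
  # the cumulative-sum variant counts both lengths
  r4s <- count_multiallelic(list(mkset(del_at(9, 10), "s1"),
                                 mkset(del_at(14, 10), "s2")), ref, overlap = "sum")
  expect_equal(r4s$affected_bp, 20L)

  # identical variant in both samples is not multi-allelic
  r5 <- count_multiallelic(list(mkset(del_at(10, 10), "s1"),
                                mkset(del_at(10, 10), "s2")), ref)
  expect_equal(r5$affected_bp, 0L)

  expect_equal(r1$genome_bp, 100L)
  expect_equal(r1$fraction, 0.1)
})

test_that("multi-allelic counting is invariant to sample order and duplication", {
  ref <- mga_genome("ref", c(chr1 = strrep("ACGT", 25)))
  refal <- substr(ref$seq[[1]], 10, 16)
  s1 <- mga_variants(tibble::tibble(chrom = "chr1", pos = 10L,
                                    ref = refal, alt = substr(refal, 1, 1),
                                    vclass = "DEL"),
                     sample = "s1", reference_id = "ref")
  s2 <- mga_variants(tibble::tibble(chrom = "chr1", pos = 12L, ref = "T", alt = "A",
                                    vclass = "SNV"),
                     sample = "s2", reference_id = "ref")
  a <- count_multiallelic(list(s1, s2), ref)
  b <- count_multiallelic(list(s2, s1), ref)
  c3 <- count_multiallelic(list(s1, s2, s2), ref)
  expect_equal(a$affected_bp, b$affected_bp)
  expect_equal(a$affected_bp, c3$affected_bp)
})

test_that("samples with disjoint variants produce no multi-allelic bases", {
  ref <- mga_genome("ref", c(chr1 = strrep("ACGT", 25)))
  s1 <- mga_variants(tibble::tibble(chrom = "chr1", pos = 5L, ref = "A", alt = "C"),
                     sample = "s1", reference_id = "ref")
  s2 <- mga_variants(tibble::tibble(chrom = "chr1", pos = 50L, ref = "C", alt = "G"),
                     sample = "s2", reference_id = "ref")
  expect_equal(count_multiallelic(list(s1, s2), ref)$affected_bp, 0L)
})
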