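test_that("column scan yields SNVs and anchored INDELs per the conventions", {
  ref <- mga_genome("ref", c(chr1 = "ACGTA"))
  vs <- extract_variants(list(mk_block("ACGTA", "ACCTA")), ref, "s")
  expect_equal(nrow(vs), 1)
  expect_equal(vs$pos, 3L); expect_equal(vs$ref, "G"); expect_equal(vs$alt, "C")
  expect_equal(vs$vclass, "SNV")

  ref2 <- mga_genome("ref", c(chr1 = "ACGGT"))
  del <- extract_variants(list(mk_block("ACGGT", "A--GT")), ref2, "s")
  expect_equal(del$pos, 1L); expect_equal(del$ref, "ACG"); expect_equal(del$alt, "A")
  expect_equal(del$vclass, "DEL")

  ref3 <- mga_genome("ref", c(chr1 = "ACGT"))
  ins <- extract_variants(list(mk_block("AC--GT", "ACTTGT")), ref3, "s")
  expect_equal(ins$pos, 2L); expect_equal(ins$ref, "C"); expect_equal(ins$alt, "CTT")
  expect_equal(ins$vclass, "INS")

  none <- extract_variants(list(mk_block("ACGT", "ACGT")), ref3, "s")
  expect_equal(nrow(none), 0)

  # N columns emit nothing
  refN <- mga_genome("ref", c(chr1 = "ANGT"))
  nn <- extract_variants(list(mk_block("ANGT", "ACGT")), refN, "s")
  expect_equal(nrow(nn), 0)
})

test_that("block-leading gaps anchor on the first reference base", {
  ref <- mga_genome("ref", c(chr1 = "TTACGGT"))
  # block starts at ref position 2 (0-based) with a leading deletion
  del <- extract_variants(list(mk_block("ACGGT", "---GT", rstart = 2L, rsrc = 7L)),
                          ref, "s")
  expect_equal(del$vclass, "DEL")
  expect_equal(del$pos, 3L)               # first deleted base, 1-based
  expect_equal(del$ref, "ACGG"); expect_equal(del$alt, "G")

  ins <- extract_variants(list(mk_block("--ACGGT", "GGACGGT", rstart = 2L, rsrc = 7L)),
                          ref, "s")
  expect_equal(ins$vclass, "INS")
  expect_equal(ins$pos, 3L)
  expect_equal(ins$ref, "A"); expect_equal(ins$alt, "GGA")
})

test_that("left normalization finds the unique leftmost form and is idempotent", {
  g <- mga_genome("ref", c(chr1 = "ATTTTG"))
  v <- mga_variants(tibble::tibble(chrom = "chr1", pos = 4L, ref = "TT", alt = "T"),
                    sample = "s", reference_id = "ref")
  nv <- normalize_variants(v, g)
  # enumerate all equivalent single-T deletions in the run: positions 2..5
  # all describe the same edited string; the leftmost anchored form is pos 1
  edited <- paste0(substr(g$seq[[1]], 1, 3), substr(g$seq[[1]], 5, 6))
  for (p in 2:5) {
    alt_seq <- paste0(substr(g$seq[[1]], 1, p - 1), substr(g$seq[[1]], p + 1, 6))
    expect_identical(alt_seq, edited)
  }
  expect_equal(nv$pos, 1L); expect_equal(nv$ref, "AT"); expect_equal(nv$alt, "A")
  expect_identical(as.data.frame(normalize_variants(nv, g)), as.data.frame(nv))

  # SNVs pass through untouched
  sv <- mga_variants(tibble::tibble(chrom = "chr1", pos = 3L, ref = "T", alt = "C"),
                     sample = "s", reference_id = "ref")
  expect_identical(as.data.frame(normalize_variants(sv, g)), as.data.frame(sv))
})

test_that("normalized INDELs cannot be shifted left any further", {
  withr::with_seed(13, {
    g <- mga_genome("ref", c(chr1 = paste(
      sample(c("A", "C", "G", "T"), 500, replace = TRUE, prob = c(.4, .1, .1, .4)),
      collapse = "")))
    recs <- list()
    for (i in 1:200) {
      p <- sample(20:480, 1)
      len <- sample(1:6, 1)
      if (runif(1) < 0.5) {
        refal <- substr(g$seq[[1]], p, p + len)
        recs[[i]] <- tibble::tibble(chrom = "chr1", pos = p, ref = refal,
                                    alt = substr(refal, 1, 1))
      } else {
        base <- substr(g$seq[[1]], p, p)
        recs[[i]] <- tibble::tibble(chrom = "chr1", pos = p, ref = base,
                                    alt = paste0(base, random_seq(len)))
      }
    }
    for (i in seq_along(recs)) {
      vs <- mga_variants(recs[[i]], sample = "s", reference_id = "ref")
      nv <- normalize_variants(vs, g)
      if (nv$pos[1] > 1) {
        # one further left shift must change the edit it encodes
        lastr <- substr(nv$ref[1], nchar(nv$ref[1]), nchar(nv$ref[1]))
        lasta <- substr(nv$alt[1], nchar(nv$alt[1]), nchar(nv$alt[1]))
        expect_false(lastr == lasta, info = paste("record", i))
      }
      expect_identical(as.data.frame(normalize_variants(nv, g)), as.data.frame(nv))
    }
  })
})

test_that("INDEL length classification uses a strict 50 bp boundary", {
  mkv <- function(pos, len, cl) {
    al <- paste0("A", strrep("C", len))
    tibble::tibble(chrom = "chr1", pos = pos,
                   ref = if (cl == "DEL") al else "A",
                   alt = if (cl == "DEL") "A" else al,
                   vclass = cl)
  }
  vs <- mga_variants(dplyr::bind_rows(mkv(1L, 51, "DEL"), mkv(2L, 50, "INS"),
                                      mkv(3L, 3, "DEL")),
                     sample = "s", reference_id = "r")
  expect_equal(classify_indel(vs), c("long", "short", "short"))
  snv <- mga_variants(tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "C"),
                      sample = "s", reference_id = "r")
  expect_error(classify_indel(snv), "INDELs only")
})

test_that("variant-set comparison counts every membership cell", {
  mk <- function(pos, sample) mga_variants(
    tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "C"),
    sample = sample, reference_id = "ref")
  tab <- compare_variant_sets(list(A = mk(c(1, 2), "a"), B = mk(c(2, 3), "b")))
  expect_equal(tab$n[tab$members == "A"], 1)
  expect_equal(tab$n[tab$members == "B"], 1)
  expect_equal(tab$n[tab$members == "A&B"], 1)

  tri <- compare_variant_sets(list(A = mk(5, "a"), B = mk(5, "b"), C = mk(5, "c")))
  expect_equal(tri$n[tri$members == "A&B&C"], 1)

  empty <- mga_variants(tibble::tibble(), sample = "e", reference_id = "ref")
  tab2 <- compare_variant_sets(list(A = mk(1, "a"), E = empty))
  expect_equal(tab2$members, "A")

  bad <- mga_variants(tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "C"),
                      sample = "x", reference_id = "other")
  expect_error(compare_variant_sets(list(A = mk(1, "a"), X = bad)), "different references")
})

test_that("every SNV's REF allele matches the reference base", {
  fx <- toy_annotated_genome(n_genes = 4)
  qry <- mutate_genome(fx$genome, "q", snv_at = seq(120L, 2400L, 131L))
  blocks <- align_genomes(fx$genome, fx$annotation, qry, align_params())
  vs <- extract_variants(blocks, fx$genome, "q")
  d <- tibble::as_tibble(vs)
  snv <- d[d$vclass == "SNV", ]
  for (i in seq_len(nrow(snv)))
    expect_identical(substr(fx$genome$seq[[snv$chrom[i]]], snv$pos[i], snv$pos[i]),
                     snv$ref[i])
})
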