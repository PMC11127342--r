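# small in-code fixtures shared across test files

# a toy genome with `n_genes` well-separated genes; returns genome +
# annotation built directly (not via the simulator)
toy_annotated_genome <- function(n_genes = 5, gene_len = 300, gap = 400,
                                 id = "toy", seed = 99) {
  withr::with_seed(seed, {
    pieces <- character(0)
    rows <- list()
    cursor <- 0L
    for (i in seq_len(n_genes)) {
      spacer <- paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE), collapse = "")
      gene <- paste0("ATG",
                     paste(sample(c("A", "C", "G", "T"), gene_len - 6, replace = TRUE),
                           collapse = ""), "TAA")
      pieces <- c(pieces, spacer, gene)
      gid <- sprintf("g%02d", i)
      rows[[i]] <- tibble::tibble(
        seq = "chr1", start = cursor + gap, end = cursor + gap + gene_len,
        strand = "+",
        type = c("gene", "mRNA", "CDS"),
        feature_id = c(gid, paste0(gid, ".1"), paste0(gid, ".1c")),
        parent_id = c(NA, gid, paste0(gid, ".1")))
      cursor <- cursor + gap + gene_len
    }
    tail_sp <- paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE), collapse = "")
    g <- mga_genome(id, c(chr1 = paste(c(pieces, tail_sp), collapse = "")))
    list(genome = g, annotation = mga_features(dplyr::bind_rows(rows), genome = g))
  })
}

# mutate a genome: SNVs at given 1-based positions, plus an optional
# deletion [del_at, del_at + del_len) (0-based) — coordinates applied
# right to left
mutate_genome <- function(genome, id, snv_at = integer(0),
                          del_at = NULL, del_len = 0, ins_at = NULL, ins_seq = "") {
  s <- genome$seq[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  edits <- list()
  if (!is.null(ins_at)) edits[[length(edits) + 1L]] <- list(pos = ins_at, type = "ins")
  if (!is.null(del_at)) edits[[length(edits) + 1L]] <- list(pos = del_at, type = "del")
  ord <- order(-vapply(edits, `[[`, numeric(1), "pos"))
  for (e in edits[ord]) {
    if (e$type == "del") s <- paste0(substr(s, 1, e$pos), substr(s, e$pos + del_len + 1, nchar(s)))
    else s <- paste0(substr(s, 1, e$pos), ins_seq, substr(s, e$pos + 1, nchar(s)))
  }
  for (p in sort(snv_at, decreasing = TRUE))
    substr(s, p, p) <- rot[[substr(s, p, p)]]
  mga_genome(id, setNames(s, names(genome$seq)[1]))
}

mk_block <- function(rtext, qtext, ref_id = "ref", chrom = "chr1",
                     rstart = 0L, qstart = 0L, rsrc = NULL, qsrc = NULL) {
  rsize <- nchar(gsub("-", "", rtext, fixed = TRUE))
  qsize <- nchar(gsub("-", "", qtext, fixed = TRUE))
  mga_block(tibble::tibble(genome = c(ref_id, "qry"), seq = chrom,
                           start = c(rstart, qstart), size = c(rsize, qsize),
                           strand = "+",
                           src_size = c(rsrc %||% (rstart + rsize),
                                        qsrc %||% (qstart + qsize))),
            c(rtext, qtext))
}

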