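#' Simulation configuration
#'
#' Parameters of the plant-like genome evolution simulator. The regime it
#' emulates: genomes carrying protein-coding genes usable as alignment
#' anchors, intergenic space partly filled with copies from a small repeat
#' library (an LTR-like repeat landscape), and variation accumulated along
#' a tree as SNVs, short INDELs (geometric lengths, mean 3) and long
#' INDELs (uniform lengths in `[51, long_indel_max]`). INDELs landing in
#' coding sequence are biased towards frame-preserving (multiple-of-3)
#' lengths with probability `cds_mod3_bias`.
#'
#' Rates are per base per unit branch length, so the expected SNV
#' divergence between two genomes equals `snv_rate` times their path
#' length in the tree.
#'
#' @param seed Integer seed fixing all randomness.
#' @param tree Guide `mga_tree` with branch lengths (or a Newick string;
#'   leaf labels name the simulated genomes).
#' @param genome_length Root chromosome length in bp.
#' @param n_genes Number of non-overlapping single-CDS genes on the root.
#' @param gene_len_range Uniform bounds for gene lengths (rounded to
#'   multiples of 3).
#' @param repeat_fraction Fraction of the genome to fill with repeat
#'   copies (placed in intergenic space).
#' @param n_repeat_families Number of repeat families in the library.
#' @param repeat_len_range Uniform bounds for repeat family lengths.
#' @param snv_rate,short_indel_rate,long_indel_rate Per-base per-unit-
#'   branch-length event rates.
#' @param long_indel_max Maximum long-INDEL length (minimum is 51).
#' @param cds_mod3_bias Probability that a CDS-overlapping INDEL is forced
#'   to a multiple-of-3 length.
#' @param reference_leaf Leaf against which truth variants are recorded;
#'   defaults to the first leaf.
#' @return A list of class `mga_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tree = "((A:0.25,B:0.25):0.25,(C:0.25,D:0.25):0.25);",
                       genome_length = 200000L,
                       n_genes = 80L,
                       gene_len_range = c(300L, 1500L),
                       repeat_fraction = 0.2,
                       n_repeat_families = 5L,
                       repeat_len_range = c(200L, 1000L),
                       snv_rate = 0.01,
                       short_indel_rate = 8e-4,
                       long_indel_rate = 5e-5,
                       long_indel_max = 2000L,
                       cds_mod3_bias = 0.9,
                       reference_leaf = NULL) {
  if (is.character(tree)) {
    phy <- ape::read.tree(text = tree)
    tree <- read_newick(tree, expected_leaves = phy$tip.label)
  }
  if (any(c(snv_rate, short_indel_rate, long_indel_rate) < 0))
    abort("rates must be >= 0")
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    abort("repeat_fraction must be in [0, 1)")
  lv <- tree_leaves(tree)
  if (is.null(reference_leaf)) reference_leaf <- lv[1]
  if (!reference_leaf %in% lv) abort("reference_leaf must be a tree leaf")
  structure(list(seed = as.integer(seed), tree = tree,
                 genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 repeat_fraction = repeat_fraction,
                 n_repeat_families = as.integer(n_repeat_families),
                 repeat_len_range = as.integer(repeat_len_range),
                 snv_rate = snv_rate, short_indel_rate = short_indel_rate,
                 long_indel_rate = long_indel_rate,
                 long_indel_max = as.integer(long_indel_max),
                 cds_mod3_bias = cds_mod3_bias,
                 reference_leaf = reference_leaf),
            class = "mga_sim_config")
}

rand_seq <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one random gene: ATG + codons + stop, total length a multiple of 3
rand_gene <- function(len) {
  len <- max(9L, as.integer(round(len / 3) * 3))
  paste0("ATG", rand_seq(len - 6L), sample(c("TAA", "TAG", "TGA"), 1))
}

#' Generate the root genome
#'
#' Root sequence with `n_genes` non-overlapping single-CDS genes (start
#' and stop codons, lengths multiples of 3) separated by intergenic
#' segments; intergenic space is seeded with copies from the repeat
#' library until the requested repeat fraction of the genome is reached.
#' Deterministic under `config$seed`.
#'
#' @param config An [sim_config()].
#' @return List with `genome` ([mga_genome()]), `annotation`
#'   ([mga_features()]) and `repeats` ([region_set()]).
#' @export
generate_root <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  ng <- config$n_genes
  glen <- if (ng > 0) {
    as.integer(round(runif(ng, config$gene_len_range[1], config$gene_len_range[2]) / 3) * 3)
  } else integer(0)
  total_gene <- sum(glen)
  if (total_gene >= L)
    abort(sprintf("genes cannot fit: need genome_length > %d", total_gene))
  intergenic_total <- L - total_gene
  # split intergenic space into ng + 1 segments
  w <- diff(c(0, sort(runif(ng)), 1))
  seg_len <- floor(w * intergenic_total)
  seg_len[1] <- seg_len[1] + (intergenic_total - sum(seg_len))
  # repeat library
  fam <- map_chr(seq_len(max(config$n_repeat_families, 1L)),
                 ~ rand_seq(round(runif(1, config$repeat_len_range[1],
                                        config$repeat_len_range[2]))))
  target_repeat <- round(config$repeat_fraction * L)
  placed <- 0L
  pieces <- character(0)
  genes <- list()
  repeat_rows <- list()
  cursor <- 0L
  fill_intergenic <- function(n, cursor) {
    # fill an intergenic segment of length n, placing repeat copies while
    # the genome-wide quota lasts
    parts <- character(0); used <- 0L
    while (used < n) {
      room <- n - used
      if (placed < target_repeat && room >= 50L && config$repeat_fraction > 0) {
        f <- fam[[sample.int(length(fam), 1)]]
        cp <- substr(f, 1, min(nchar(f), room, target_repeat - placed))
        spacer <- min(room - nchar(cp), max(0L, as.integer(rpois(1, 30))))
        parts <- c(parts, rand_seq(spacer), cp)
        repeat_rows[[length(repeat_rows) + 1L]] <<- tibble(
          seq = "chr1", start = cursor + used + spacer,
          end = cursor + used + spacer + nchar(cp))
        placed <<- placed + nchar(cp)
        used <- used + spacer + nchar(cp)
      } else {
        parts <- c(parts, rand_seq(room))
        used <- n
      }
    }
    paste(parts, collapse = "")
  }
  for (i in seq_len(ng + 1L)) {
    seg <- fill_intergenic(seg_len[i], cursor)
    pieces <- c(pieces, seg)
    cursor <- cursor + seg_len[i]
    if (i <= ng) {
      g <- rand_gene(glen[i])
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") g_out <- revcomp(g) else g_out <- g
      genes[[i]] <- tibble(start = cursor, end = cursor + nchar(g), strand = strand)
      pieces <- c(pieces, g_out)
      cursor <- cursor + nchar(g)
    }
  }
  genome <- mga_genome("root", c(chr1 = paste(pieces, collapse = "")))
  feats <- if (ng > 0) {
    gd <- bind_rows(genes)
    gid <- sprintf("gene%03d", seq_len(ng))
    mga_features(bind_rows(
      tibble(seq = "chr1", start = gd$start, end = gd$end, strand = gd$strand,
             type = "gene", feature_id = gid, parent_id = NA_character_),
      tibble(seq = "chr1", start = gd$start, end = gd$end, strand = gd$strand,
             type = "mRNA", feature_id = paste0(gid, ".1"), parent_id = gid),
      tibble(seq = "chr1", start = gd$start, end = gd$end, strand = gd$strand,
             type = "CDS", feature_id = paste0(gid, ".1.cds"),
             parent_id = paste0(gid, ".1"))), genome = genome)
  } else {
    mga_features(tibble(seq = character(), start = integer(), end = integer(),
                        strand = character(), type = character(),
                        feature_id = character(), parent_id = character()))
  }
  repeats <- region_set(if (length(repeat_rows)) bind_rows(repeat_rows)
                        else tibble(seq = character(), start = integer(), end = integer()),
                        label = "repeat")
  list(genome = genome, annotation = feats, repeats = repeats)
}

# sample one indel length under the CDS frame bias
indel_len <- function(kind, in_cds, config) {
  len <- if (kind == "short") rgeom(1, 1 / 3) + 1L
         else sample(51:config$long_indel_max, 1)
  if (in_cds && runif(1) < config$cds_mod3_bias) {
    len <- as.integer(max(3L, round(len / 3) * 3))
    if (kind == "long") len <- max(51L, len)
  }
  as.integer(len)
}

#' Evolve a genome along one branch
#'
#' SNV and INDEL counts are Poisson with mean `rate * branch_length *
#' sequence length`; short INDEL lengths are geometric (mean 3), long
#' INDEL lengths uniform in `[51, long_indel_max]`; INDELs overlapping a
#' CDS are resampled to a multiple-of-3 length with probability
#' `cds_mod3_bias`. Edits are applied right to left so earlier coordinates
#' stay valid. Uses the current RNG state (seed at the caller).
#'
#' @param parent List with `genome` ([mga_genome()]) and `annotation`
#'   ([mga_features()]) of the parent.
#' @param branch_length Branch length to the child.
#' @param config An [sim_config()].
#' @return List with child `genome`, `annotation` (coordinates lifted
#'   through the edits), `edits` (tibble of events in parent coordinates:
#'   `seq`, `pos` 1-based, `type`, `len`) and `parent_map` (per child
#'   sequence, the 1-based parent position of every child base, `NA` for
#'   inserted bases).
#' @export
evolve_branch <- function(parent, branch_length, config) {
  genome <- parent$genome
  ann <- parent$annotation
  cds <- ann[ann$type == "CDS", ]
  out_seq <- character(); out_map <- list(); edits <- list()
  for (chrom in names(genome$seq)) {
    chars <- strsplit(genome$seq[[chrom]], "", fixed = TRUE)[[1]]
    L <- length(chars)
    pmap <- seq_len(L)
    n_snv <- rpois(1, config$snv_rate * branch_length * L)
    n_short <- rpois(1, config$short_indel_rate * branch_length * L)
    n_long <- rpois(1, config$long_indel_rate * branch_length * L)
    cds_ir <- IRanges::IRanges(start = cds$start[cds$seq == chrom] + 1L,
                               end = cds$end[cds$seq == chrom])
    ev <- list()
    if (n_snv > 0) {
      pos <- sample.int(L, min(n_snv, L))
      ev[[length(ev) + 1L]] <- tibble(pos = pos, type = "SNV", len = 1L)
    }
    mk_indels <- function(n, kind) {
      if (n <= 0) return(NULL)
      pos <- sample.int(L, min(n, L))
      in_cds <- IRanges::overlapsAny(IRanges::IRanges(start = pos, width = 1L), cds_ir)
      tibble(pos = pos,
             type = sample(c("INS", "DEL"), length(pos), replace = TRUE),
             len = map_int(seq_along(pos), ~ indel_len(kind, in_cds[.x], config)))
    }
    ev[[length(ev) + 1L]] <- mk_indels(n_short, "short")
    ev[[length(ev) + 1L]] <- mk_indels(n_long, "long")
    ev <- bind_rows(ev)
    if (nrow(ev)) {
      ev <- arrange(ev, desc(.data$pos))
      for (i in seq_len(nrow(ev))) {
        p <- ev$pos[i]; len <- ev$len[i]
        if (p > length(chars)) next  # landed in a segment removed by an earlier edit
        if (ev$type[i] == "SNV") {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        } else if (ev$type[i] == "DEL") {
          hi <- min(L0 <- length(chars), p + len - 1L)
          keep <- c(seq_len(p - 1L), if (hi < L0) (hi + 1L):L0)
          chars <- chars[keep]; pmap <- pmap[keep]
        } else {
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          chars <- append(chars, ins, after = p)
          pmap <- append(pmap, rep(NA_integer_, len), after = p)
        }
      }
    }
    out_seq[[chrom]] <- paste(chars, collapse = "")
    out_map[[chrom]] <- pmap
    edits[[chrom]] <- if (nrow(ev)) mutate(ev, seq = chrom) else NULL
  }
  child_genome <- mga_genome(genome$genome_id, out_seq,
                             masked_fraction = genome$masked_fraction)
  # lift annotation through the edit map
  new_feats <- list()
  for (i in seq_len(nrow(ann))) {
    pm <- out_map[[ann$seq[i]]]
    hit <- which(!is.na(pm) & pm >= ann$start[i] + 1L & pm <= ann$end[i])
    if (length(hit) < 0.5 * (ann$end[i] - ann$start[i])) next  # feature destroyed
    new_feats[[length(new_feats) + 1L]] <- tibble(
      seq = ann$seq[i], start = min(hit) - 1L, end = max(hit),
      strand = ann$strand[i], type = ann$type[i],
      feature_id = ann$feature_id[i], parent_id = ann$parent_id[i])
  }
  nf <- if (length(new_feats)) bind_rows(new_feats) else
    tibble(seq = character(), start = integer(), end = integer(),
           strand = character(), type = character(),
           feature_id = character(), parent_id = character())
  # drop CDS/mRNA whose parents were destroyed
  keep_ids <- nf$feature_id
  nf <- nf[is.na(nf$parent_id) | nf$parent_id %in% keep_ids, ]
  list(genome = child_genome, annotation = mga_features(nf, genome = child_genome),
       edits = bind_rows(edits), parent_map = out_map)
}

#' Simulate genomes along a guide tree with truth variants
#'
#' The root genome is generated and evolved down the tree; per-leaf truth
#' variants versus the designated reference leaf are derived by composing
#' the per-branch coordinate maps through the root (so nested events
#' collapse into the outer event's record) and normalizing. Truth
#' alignment intervals (syntenic spans never disrupted on either path) are
#' recorded per leaf.
#'
#' @param config An [sim_config()].
#' @return List of class `mga_simulation`: `genomes`, `annotations`
#'   (named by leaf), `tree`, `repeats` (root repeat regions),
#'   `reference_leaf`, `truth` (per non-reference leaf: `variants`, an
#'   [mga_variants()]; `spans`, a tibble of 0-based half-open syntenic
#'   intervals on the reference).
#' @export
simulate_genomes <- function(config) {
  root <- generate_root(config)  # seeds the RNG with config$seed itself
  # walk the tree depth-first, evolving each branch; root map is identity
  nodes <- list()
  walk <- function(node, parent_state) {
    state <- if (is.null(parent_state)) {
      list(genome = root$genome, annotation = root$annotation,
           root_map = lapply(genome_lengths(root$genome), seq_len))
    } else {
      bl <- node$length
      if (is.null(bl) || is.na(bl)) bl <- 0.1
      ev <- evolve_branch(parent_state, bl, config)
      rm <- list()
      for (chrom in names(ev$parent_map))
        rm[[chrom]] <- parent_state$root_map[[chrom]][ev$parent_map[[chrom]]]
      list(genome = ev$genome, annotation = ev$annotation, root_map = rm)
    }
    if (!length(node$children)) {
      state$genome$genome_id <- node$id
      nodes[[node$id]] <<- state
    } else {
      for (ch in node$children) walk(ch, state)
    }
    invisible(NULL)
  }
  walk(config$tree, NULL)
  leaves <- tree_leaves(config$tree)
  genomes <- lapply(nodes, `[[`, "genome")[leaves]
  annotations <- lapply(nodes, `[[`, "annotation")[leaves]
  ref_leaf <- config$reference_leaf
  params <- align_params()
  truth <- list()
  ref_state <- nodes[[ref_leaf]]
  for (lf in setdiff(leaves, ref_leaf)) {
    qs <- nodes[[lf]]
    blocks <- list(); spans <- list()
    for (chrom in names(root$genome$seq)) {
      rootlen <- nchar(root$genome$seq[[chrom]])
      inv_r <- rep(NA_integer_, rootlen)
      mr <- ref_state$root_map[[chrom]]
      inv_r[mr[!is.na(mr)]] <- which(!is.na(mr))
      inv_q <- rep(NA_integer_, rootlen)
      mq <- qs$root_map[[chrom]]
      inv_q[mq[!is.na(mq)]] <- which(!is.na(mq))
      co <- which(!is.na(inv_r) & !is.na(inv_q))
      if (!length(co)) next
      bl <- pairs_to_blocks(inv_r[co], inv_q[co], ref_state$genome, chrom,
                            qs$genome, chrom, params)
      blocks <- c(blocks, bl)
      for (b in bl)
        spans[[length(spans) + 1L]] <- tibble(
          seq = chrom, start = b$rows$start[1],
          end = b$rows$start[1] + b$rows$size[1])
    }
    vs <- extract_variants(blocks, ref_state$genome, sample = lf)
    vs <- normalize_variants(vs, ref_state$genome)
    truth[[lf]] <- list(variants = vs,
                        spans = if (length(spans)) bind_rows(spans)
                                else tibble(seq = character(), start = integer(),
                                            end = integer()))
  }
  structure(list(genomes = genomes, annotations = annotations,
                 tree = config$tree, repeats = root$repeats,
                 reference_leaf = ref_leaf, truth = truth,
                 config = config),
            class = "mga_simulation")
}

#' @export
print.mga_simulation <- function(x, ...) {
  cat(sprintf("<mga_simulation> %d leaves (%s), reference %s, %d truth set(s)\n",
              length(x$genomes), paste(names(x$genomes), collapse = ", "),
              x$reference_leaf, length(x$truth)))
  invisible(x)
}
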