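#' Call variants for every leaf against a reference leaf
#'
#' Projects the hierarchy into a reference-anchored pairwise alignment per
#' non-reference leaf, extracts variants and left-normalizes them.
#'
#' @param h An [mga_hierarchy()].
#' @param ref_leaf Reference leaf genome id.
#' @param params An [align_params()] object.
#' @return Named list of normalized [mga_variants()] sets, one per
#'   non-reference leaf.
#' @export
call_variants <- function(h, ref_leaf, params = align_params()) {
  leaves <- tree_leaves(h$tree)
  ref_genome <- h$nodes[[ref_leaf]]$genome
  out <- list()
  for (lf in setdiff(leaves, ref_leaf)) {
    blocks <- project_pairwise(h, ref_leaf, lf, params)
    vs <- extract_variants(blocks, ref_genome, sample = lf)
    out[[lf]] <- normalize_variants(vs, ref_genome)
  }
  out
}

#' Score called variants against a simulator truth set
#'
#' SNVs match on exact `(chrom, pos, ref, alt)`. INDELs match on class and
#' exact length within a positional tolerance (default 5 bp), the
#' resolution at which a re-aligned event is considered recovered.
#' Evaluation is restricted to the truth's syntenic spans.
#'
#' @param called An [mga_variants()] set.
#' @param truth A truth entry from [simulate_genomes()] (`variants` +
#'   `spans`).
#' @param pos_tol Positional tolerance for INDEL matching.
#' @return Tibble with one row per class (`SNV`, `short_indel`,
#'   `long_indel`): `n_truth`, `n_called`, `n_matched`, `recall`,
#'   `precision`.
#' @export
score_calls <- function(called, truth, pos_tol = 5L) {
  spans <- truth$spans
  in_spans <- function(d) {
    if (!nrow(d)) return(logical(0))
    keep <- rep(FALSE, nrow(d))
    for (chrom in unique(d$chrom)) {
      sel <- which(d$chrom == chrom)
      sp <- spans[spans$seq == chrom, ]
      if (!nrow(sp)) next
      ir <- IRanges::IRanges(start = sp$start + 1L, end = sp$end)
      keep[sel] <- IRanges::overlapsAny(
        IRanges::IRanges(start = d$pos[sel], width = 1L), ir)
    }
    keep
  }
  cd <- as_tibble(called); td <- as_tibble(truth$variants)
  cd <- cd[in_spans(cd), ]; td <- td[in_spans(td), ]
  cls <- function(d) ifelse(d$vclass == "SNV", "SNV",
                            ifelse(abs(nchar(d$ref) - nchar(d$alt)) > 50,
                                   "long_indel", "short_indel"))
  cd$cls <- if (nrow(cd)) cls(cd) else character(0)
  td$cls <- if (nrow(td)) cls(td) else character(0)
  rows <- lapply(c("SNV", "short_indel", "long_indel"), function(cl) {
    cc <- cd[cd$cls == cl, ]; tt <- td[td$cls == cl, ]
    if (cl == "SNV") {
      key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
      matched <- sum(key(tt) %in% key(cc))
      called_ok <- sum(key(cc) %in% key(tt))
    } else {
      used <- rep(FALSE, nrow(cc))
      matched <- 0L
      lenv <- function(d) abs(nchar(d$ref) - nchar(d$alt))
      for (i in seq_len(nrow(tt))) {
        cand <- which(!used & cc$chrom == tt$chrom[i] &
                        cc$vclass == tt$vclass[i] &
                        lenv(cc) == lenv(tt)[i] &
                        abs(cc$pos - tt$pos[i]) <= pos_tol)
        if (length(cand)) { used[cand[1]] <- TRUE; matched <- matched + 1L }
      }
      called_ok <- sum(used)
    }
    tibble(class = cl, n_truth = nrow(tt), n_called = nrow(cc),
           n_matched = matched,
           recall = if (nrow(tt)) matched / nrow(tt) else NA_real_,
           precision = if (nrow(cc)) called_ok / nrow(cc) else NA_real_)
  })
  bind_rows(rows)
}

#' Run simulation, progressive alignment and variant calling end to end
#'
#' Convenience wrapper: simulate genomes, align them progressively along
#' the simulated tree, call variants against the simulation's reference
#' leaf and score them against the truth sets.
#'
#' @param config An [sim_config()].
#' @param params An [align_params()] object.
#' @return List with `sim`, `hierarchy`, `calls` and `scores` (tibble with
#'   a `sample` column).
#' @export
run_pipeline <- function(config, params = align_params()) {
  sim <- simulate_genomes(config)
  h <- progressive_align(sim$genomes, sim$annotations, sim$tree, params)
  calls <- call_variants(h, sim$reference_leaf, params)
  scores <- bind_rows(lapply(names(sim$truth), function(lf) {
    mutate(score_calls(calls[[lf]], sim$truth[[lf]]), sample = lf)
  }))
  list(sim = sim, hierarchy = h, calls = calls, scores = scores)
}
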