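Package: minimga
Title: Reference-Free Progressive Multiple Genome Alignment with Gene
    Anchors and Two-Piece Affine Gap Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for reference-free multiple genome
    alignment of small (desk-scale) assemblies. Pairwise alignment anchors
    on protein-coding genes, chains anchors into collinear blocks, and
    aligns anchor and inter-anchor intervals globally under a two-piece
    affine gap cost so long insertions and deletions are charged
    near-linearly. Genomes are combined progressively along a guide tree
    through reconstructed ancestral sequences; the resulting hierarchy is
    projected into reference-anchored pairwise alignments from which
    normalized SNV and INDEL calls are extracted. Includes the evaluation
    statistics used for such aligners (position-match and aligned-base
    counts per region class, INDEL length spectra with mod-3 coding-region
    enrichment, multi-allelic base-pair accounting) and a genome-evolution
    simulator that emits truth variants for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    stats,
    utils,
    ape,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
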