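---
title: "Reference-free progressive genome alignment with minimga: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free progressive genome alignment with minimga: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minimga)
```

## The problem

Plant genome comparisons face two compounding difficulties: a large
fraction of the genome is repetitive (LTR retrotransposons dominate in
large genomes), and individuals of one species differ not only by SNVs and
short INDELs but also by long insertions and deletions (here, "long" means
strictly more than 50 bp). Short-read variant calling recovers almost none
of the long events; pairwise whole-genome alignment against a single
reference discards variation private to non-reference accessions. minimga
implements, at desk scale, a reference-free multiple-genome-alignment
(MGA) strategy: many small pairwise alignment subproblems arranged along a
guide tree, joined through reconstructed ancestral genomes, and projected
back to any reference for variant extraction and evaluation.

## Pairwise alignment model

The pairwise engine is anchor-based and global. Protein-coding genes
supply the anchors: one spliced CDS per gene (the longest mRNA), located
in the other genome by exact 15-mer seeding plus banded extension, kept
when placement identity reaches `min_anchor_identity` (default 0.9) and
dropped as repetitive-ambiguous when more than three placements fall
within 2% identity of the best. Anchors are chained by dynamic programming
into collinear blocks (strictly increasing coordinates on both genomes;
transition penalty `E2 * |ref_gap - qry_gap| + 1`), and every anchor and
inter-anchor interval is aligned *globally*, so diverged and repetitive
interludes are aligned rather than skipped.

Gap runs are charged with a two-piece affine cost

\[ w(L) = \min(O_1 + E_1 L,\; O_2 + E_2 L), \qquad
   O_1 = 8,\ E_1 = 2,\ O_2 = 80,\ E_2 = 1, \]

with `match = 2`, `mismatch = 4`. The second regime opens expensively and
extends cheaply, so a long INDEL is kept as a single event rather than
fragmented — under the defaults the long-gap regime takes over at
\(L = 73\). The five-state DP (one match state, two gap regimes per
sequence) is exact; a regime switch inside one run is representable but
never optimal because the cost is subadditive, so the DP optimum equals
the optimum of whole-run scoring. Ties break deterministically (diagonal,
then gap-in-query, then gap-in-reference; extension before re-opening),
making every output byte-reproducible.

### Numerical and scale choices

Interval pairs up to `max_full_cells` (default 2.5 million DP cells) are
solved exactly; larger ones use a band that always covers the length
difference plus `band_width` (96) diagonals. Because a banded DP cannot
represent an interval whose true layout needs offsets outside the band
(e.g. an insertion and a deletion of several hundred bp each inside one
interval), long intervals are first pinned by *local anchoring*: maximal
runs of exact 31-mers unique within both interval sequences (at least
50 bp) are chained and the segments between them aligned recursively.
This matters most in repeat fields, where globally repeated sequence is
still locally unique. Intervals longer than `max_interanchor_len`
(20,000 bp) on either side are declared unalignable and split the block.

Two further guards keep mis-alignment out of downstream variant calls:

* a segment pair whose alignment shows less than `min_junction_identity`
  (0.7) identity over its ungapped columns is treated as non-homologous
  and represented as a deletion plus an insertion — mismatch soup between
  unrelated sequences would otherwise masquerade as dense SNVs;
* chain-end extensions (the aligner extends beyond the outermost anchors
  toward the sequence ends, and bridges consecutive monotone chains) keep
  only their maximum-scoring core, computed by a Kadane scan over
  alignment units. This also removes a terminal-tie artifact in which a
  global DP matches the last base across a long gap at equal score.

Extensions are additionally aligned with a wide band
(`extension_band = 2048`), because their one-sided anchoring means the
interval length difference says nothing about interior indels.

Soft-masking in input FASTA is recorded (`masked_fraction`) but never used
to suppress anchors or seeds: anchoring on genes does not need repeat
masking, and suppressing masked seeds would prevent alignment from
initiating inside repeat regions at all.

## Progressive combination and ancestors

The guide tree (supplied as Newick, or estimated by UPGMA over
1 − Jaccard distances of canonical 21-mer sets) is traversed post-order.
At each internal node the two children are aligned pairwise and an
ancestral genome is assembled:

* the left child is the backbone — every left position is carried into
  the ancestor (aligned blocks and the unaligned segments between them),
  so no backbone position becomes unreachable from the root;
* at aligned columns the ancestor takes the left child's base (with only
  two children there is no outgroup to arbitrate a mismatch; the choice
  cancels out in leaf-versus-leaf projection, which always reads bases
  from the leaves);
* right-child insertions up to `max_keep_insert` (5,000 bp) are retained
  so orthologous insertions can align at later iterations; longer ones
  are omitted to bound ancestor growth;
* right-child segments used by no block are appended as extra ancestor
  sequences (`<node>_accN`), never silently discarded.

Child CDS features are lifted through the column maps (kept at ≥ 80%
projected coverage; overlapping projections from the two children merged),
so each ancestor carries the merged CDS set that anchors the next
iteration.

Each node stores per-child column maps (ancestor position → child
position, strictly monotone where defined). Projection of the hierarchy
onto any leaf pair composes these maps through the lowest common ancestor;
maximal runs of co-mapped columns become two-row MAF blocks forced to the
positive strand of both genomes. Junction material between co-mapped
columns that exists in only one leaf becomes a pure gap run; material
present in both leaves is re-aligned locally (same engine, same identity
gate), keeping every emitted row an exact substring of its genome.
Inversions are detected as minus-strand anchor chains but left unaligned:
the downstream variant accounting operates on positive-strand projections
only.

## Variant extraction and normalization

A column scan of each projected block emits SNVs at mismatch columns
(separate records, never MNPs) and INDELs for maximal gap runs, anchored
on the preceding reference base; a block-leading run is anchored on the
first reference base of the block with that base included in both alleles.
Columns containing `N` emit nothing. INDELs are left-aligned and trimmed
to the unique leftmost parsimonious representation (idempotent, and stable
in the sense that no further left shift is possible). An INDEL is *long*
iff its length exceeds 50 bp — 51 is long, 50 is short. Variants are
called only inside projected blocks; unaligned segments yield no records,
since missing alignment may itself reflect structural variation.

## Evaluation statistics

* **Position match / aligned bp.** For each reference position inside a
  region class (CDS, genic, repeat, whole genome), coverage is the number
  of alignment columns where both rows are ungapped. `position_match_bp`
  counts positions covered at least once (a position match is an ungapped
  column, matched *or* mismatched); `aligned_bp` sums coverage with
  multiplicity, i.e. a depth sum. The two are additive over any partition
  of the genome.
* **INDEL length spectrum.** INDEL lengths are binned (1..50, >50); the
  fraction with length divisible by three is contrasted inside versus
  outside CDS — frame-preserving events are tolerated in coding sequence —
  with a two-sided binomial test of the CDS fraction against the non-CDS
  fraction.
* **Multi-allelic accounting.** A locus is multi-allelic when footprints
  of two or more distinct alleles intersect (a deletion covers its deleted
  interval; an SNV its site; an insertion its anchor base). Deletions
  participating in any such locus contribute their full deleted interval;
  a locus whose participants are all SNVs/insertions contributes one base
  pair. Overlapping deletion footprints are combined as a *union* by
  default — a fraction of the genome cannot exceed one — with the
  cumulative *sum* available via `overlap = "sum"` for comparison.

## The simulator and what passing tests mean

`simulate_genomes()` emulates the regime the aligner targets: a root
genome with non-overlapping single-CDS genes (start/stop codons, lengths
multiples of three) and intergenic space partly filled from a small
library of repeat families; SNVs, short INDELs (geometric lengths, mean
3) and long INDELs (uniform in [51, 2,000]) accumulate along the guide
tree, with CDS-overlapping INDELs biased to multiples of three with
probability 0.9. Defaults: 200 kb, 80 genes, 20% repeat content, rates
per base per unit branch length of 0.01 (SNV), 8×10⁻⁴ (short INDEL) and
5×10⁻⁵ (long INDEL), on a balanced 4-leaf tree with 0.25-length branches
— so leaf pairs diverge by 0.5–1% SNV. Truth variants versus a designated
reference leaf are derived by composing per-branch coordinate maps
through the root, so nested events collapse into the outer event's
record, and truth is restricted to syntenic spans.

The simulator is deliberately simple: uniform mutation rates, no
rate heterogeneity, no inversions/translocations/polyploidy, exact repeat
copies at the root, single-chromosome genomes. Passing its end-to-end
checks therefore shows that the machinery is correct under a clean model
of the target regime; it does not demonstrate performance on real
assemblies, where repeat structure, segmental duplication and
rearrangement are far richer.

At the default study size (4 leaves × 200 kb) a full
simulate–align–call–score run takes about one to two minutes on one CPU;
the test suite uses 20–50 kb genomes for unit-level checks and the full
size for end-to-end ones.

## Design choices that were genuinely open

* **Ancestor base at mismatch columns** — left child wins. A two-child
  subproblem has no outgroup for parsimony; the label cancels out in
  projection.
* **Backbone completeness** — the retention cap applies to right-child
  insertions only; left-child (backbone) segments are always carried.
  Dropping backbone runs would make leaf sequence unreachable from the
  root and silently truncate projections.
* **"Cumulative length" of overlapping deletions** — union, not sum
  (both implemented). The reported statistic is a fraction of the genome,
  which a sum could push past 1.
* **Multi-allelic SNV-only loci** — counted once per locus, not once per
  allele.
* **One pairwise alignment per internal node.** Schemes that re-align
  each subproblem in multiple rounds with outgroup genomes are specific
  to other toolchains; a single child-child alignment per node keeps the
  hierarchy explicit and the run deterministic.
* **Guide-tree estimation** is plumbing, not a contribution: canonical
  k-mer Jaccard distances plus UPGMA, with lexicographic tie-breaking for
  determinism.

## Known limitations

Inversions and translocations are detected only insofar as minus-strand
chains and non-monotone anchors are excluded from alignment; their
variants are not called. Genotypes are haploid presence/absence; there
are no likelihoods. Repeat fields with no locally unique sequence cannot
be pinned and fall back to gated global alignment, which may leave such
an interval represented as a deletion-plus-insertion pair rather than a
column-wise alignment. Anchor placement treats a multi-exon CDS as its
genomic span, which is adequate for compact genes but would blur anchors
with very long introns.
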