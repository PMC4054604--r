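---
title: "tircat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tircat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tircat)
```

## The problem

Many long noncoding RNAs (lncRNAs) initiate not from canonical promoters
but from enhancer elements. The two origins can be distinguished by the
chromatin at the transcript's initiation region: enhancers carry
relatively more H3K4 mono-methylation (H3K4me1) than tri-methylation
(H3K4me3), promoters the reverse. `tircat` implements, as reusable tested
components, a pipeline that

1. builds *transcriptional initiation regions* (TIRs) from strand-specific
   5'-end sequencing tags (CAGE-type data),
2. classifies each TIR as enhancer-like or promoter-like from the
   H3K4me1 - H3K4me3 balance,
3. partitions intergenic lncRNAs into enhancer-associated (*elncRNA*) and
   promoter-associated (*plncRNA*) classes, and
4. computes the downstream comparative statistics: tissue specificity,
   the neighbor-expression fold difference (the delta statistic),
   permutation enrichment in gene territories, and selective constraint
   against G+C-matched ancestral repeats.

Every input can be produced by the synthetic generator
(`simulate_bundle()`), which plants full ground truth, so all claims made
by the test suite are claims about recovery of planted structure.

## TIR calling

Tag 5'-end positions on the same strand are chained by single linkage
when they lie within `max_gap = 20` bp of each other; clusters whose
edge-to-edge gap is at most `merge_dist = 400` bp are merged transitively
into TIRs. TIRs with fewer than `min_reads = 5` supporting tags, or
without at least `min_overlap = 1` bp of overlap with a DNase I
hypersensitive site, are discarded.

Two boundary conventions were genuinely open and are fixed as follows:

* **Inclusive boundaries.** "Within 20 bp" and "within 400 bp" are read
  inclusively: a gap of exactly 20 (resp. 400) joins. The constants are
  exposed as arguments.
* **"Overlap by more than one nucleotide"** for DHS gating is read as
  *any* overlap (>= 1 bp), because the minimal detectable overlap is one
  base and the same phrase is used interchangeably with "one or more
  nucleotides" elsewhere in the source procedure. For CpG islands, where
  the phrase stands alone, the strict reading (>= 2 bp) is used. Both are
  configuration knobs (`min_overlap`).
* The 400-bp merge distance is measured **edge-to-edge** (not
  midpoint-to-midpoint); this is the natural reading for intervals of
  very different widths.

TIR-transcript association requires exon overlap, strand agreement, *and*
intersection with a +-50 bp window around the transcript's 5' end, so that
tags over internal exons cannot claim a transcript. Mono-exonic,
strand-unknown transcript models are linked only when exactly one of their
two possible 5' ends has a candidate TIR; the strand is then imputed so
that end is 5'. Models with candidates at both ends are dropped as
ambiguous rather than guessed.

## Chromatin classification

For each region the per-million-normalised coverage of each mark is
summed in a `window = 2000` bp window centred on the region midpoint
(`quantify_mark()`); the reference enrichment procedure is not restated in
the source, so this standard windowed per-million quantification was
chosen and the window is configurable. The label is the *sign* of
`me1 - me3` on normalised scores; exact ties are labelled `ambiguous` and
excluded from class-level statistics rather than forced into a class,
because forcing a tie invents information. No margin around zero is
applied by default (none is described); the pseudocount (default 1)
affects only the reported log2 ratio, never the label. No input-DNA
background correction is performed.

`signal_matrix()` (region x offset heatmap input), `metaprofile()`
(strand-flipped column means so positive offsets always point downstream
of transcription), `stranded_tss_profile()` (sense/antisense tag counts
around TSSs) and `tag_density_track()` (100-bp/10-bp sliding window)
reproduce the display computations. Out-of-chromosome bases contribute
zero coverage, so matrix row sums times the bin width equal the clipped
window totals exactly.

## The lncRNA catalogue

The decision tree, applied to TIR-linked transcripts:

* *intragenic*: >= 1 bp any-strand overlap with a coding gene body;
* *bidirectional*: the transcript's TIR lies on the opposite strand within
  1,000 bp (edge-to-edge) of a coding-gene TIR, or overlaps one. The
  window is not specified by the source; 1 kb was chosen to exceed the
  400-bp merge distance with margin and is configurable;
* *intergenic* otherwise. Intergenic transcripts pass the lncRNA filter
  when their **mature (spliced) length** strictly exceeds 200 nt ("long
  noncoding RNA" refers to the transcript, not the genomic span), they are
  flagged noncoding, and they do not overlap pseudogene annotation.

Class assignment maps the TIR label directly: enhancer-like gives
elncRNA, promoter-like plncRNA, ambiguous none. Transposable-element
density is computed both over TIRs and over exons (the source is
internally inconsistent about which was used; both are reported, neither
privileged). When a transcript has several linked TIRs, the
best-supported one is used (ties by id).

## Expression statistics

Tissue specificity is the fractional-expression score
`Ts_i = x_i / sum(x)` with `maxTs = max(Ts)`; this definition (rather
than the fold-over-median variant, which is exposed as
`fold_over_median`) is the default because its reported medians lie in
[0, 1]. "Detected" means strictly greater than a configurable threshold,
default 0.

`tmm_factors()` is a deliberately simplified, unweighted
trimmed-mean-of-M-values: M and A are computed on raw counts over loci
expressed in both libraries, the central 60% by M and by A is kept, and
the factor `2^mean(M)` acts as an effective library-size ratio (dividing
counts by it equalises the stably expressed core). This diverges from
edgeR's precision-weighted implementation; a cross-check test confirms
the two agree on effective library size to < 0.1 log2 on clean data.
Down-sampling is exact multivariate hypergeometric sampling without
replacement. Constitutive exons are the bases shared by all isoforms,
falling back to the exon union with a warning when the intersection is
empty.

## Neighbor association

Gene territories split intergenic gaps at their midpoint (edge-to-edge
base distance, ties to the upstream gene); overlapping genes are merged
into one territory holder. Territories provably tile each chromosome
that carries a gene.

Permutation enrichment re-places intervals of the observed lengths
uniformly at random within the intergenic workspace (independent draws;
placements may overlap each other), and reports the add-one empirical
p-value `(1 + #[perm >= obs]) / (n_perm + 1)`, which never returns 0.
Queries are counted with multiplicity (two lncRNAs in one territory count
twice); whole-interval overlap is the default statistic, midpoint
membership is available via `mode = "midpoint"`.

The delta statistic takes the stages where the *reference* locus is
maximal/minimal (ties to the earliest stage) and reports the neighbor's
relative change between them, with both neighbor values floored at
`epsilon = 0.01` expression units so the ratio is always defined (a
neighbor rising from 0 to 1 gives delta = 99). Group comparisons use the
two-tailed Mann-Whitney test (exact for small tie-free samples).

## Molecular evolution

Pairwise distances come from closed-form estimators on the joint
site-pattern matrix (gap/N columns excluded): JC69, K80, and the
generalised (paralinear/REV-family) distance
`d = -trace(Pi log(Pi^-1 F))` on the symmetrised joint frequency matrix.
An external phylogenetics binary is deliberately not shelled out to; the
test suite instead checks the closed form against a brute-force
maximum-likelihood grid. On numerical failure (non-positive eigenvalues
near saturation) the estimator falls back GTR -> K80 -> JC69 and records
the model actually used; saturated alignments raise an error.

Each element's neutral reference pools the site patterns of
non-overlapping ancestral repeats anchored within 500 kb whose G+C
content is within +-0.05 of the element's; when none matches, the single
nearest-GC repeat in range is used with a warning (the exact matching bin
widths of the original procedure are not restated in the source; these
choices are flagged as this package's own). Pooling (rather than
per-repeat averaging) stabilises short repeats. Constraint is the
element/AR rate ratio; values below 1 indicate purifying selection.

## The synthetic world

`simulation_config()` fixes the stated world: 2 chromosomes of 1 Mb,
30 coding genes and 20 intergenic lncRNAs laid out so every lncRNA is
flanked by coding genes; negative-binomial tag counts (mean 50,
dispersion 2) with 5-bp Gaussian positional jitter; 300-bp DHS peaks over
true TSSs; H3K4me1:me3 ratios of 4:1 (enhancer-like) vs 1:4
(promoter-like) at Poisson depth 100 over a triangular +-1 kb profile; a
10-tissue panel with Dirichlet concentration 0.2 (elncRNA) vs 2.0
(plncRNA); 3 erythroid-style stages with neighbor coupling alpha = 1 for
elncRNAs and 0 for plncRNAs; and JC-evolved alignment pairs at the
neutral rate 0.165 substitutions/site with a 0.8 rate factor (20%
constraint) for plncRNA TIRs. Class allocation is deterministic (exact
counts) by default for stable fixtures. Where the source states a value
(20/400/5 bp thresholds, 0.165 neutral rate, 20% constraint, 60% stable
fraction) the generator uses it; remaining values are one-time choices of
plausible magnitudes and are not revisited.

What the generator does **not** emulate: mappability artefacts,
PCR duplicates, copy-number variation, indels in alignments (available
via an optional mode of `evolve_pair` semantics but off by default),
isoform complexity beyond two isoforms, and background transcriptional
noise between loci. A green test therefore establishes correctness of the
algorithms on idealised inputs with planted truth, not robustness to
every artefact of real libraries.

## Numerical and degenerate-input conventions

* Internal coordinates are 0-based half-open everywhere (BED native);
  GTF is converted on read and write.
* All outputs are sorted by (chrom, start, strand); ids are assigned in
  that order, so runs are deterministic given the seed.
* Empty inputs yield empty outputs (never errors) for clustering,
  merging, filtering and density operations; statistical operations that
  need data (correlations, rank tests, metaprofiles) error on fewer than
  the minimal number of observations.
* The nearest-feature tie-break is leftmost start, then lexicographic
  name.
* All Monte-Carlo machinery (down-sampling, permutation placement,
  simulation) is seeded explicitly and restores the caller's RNG state.

## Known limitations

* The chromatin classifier compares per-million-normalised scores, so a
  large library-size imbalance between the two marks shifts the implicit
  decision boundary; the planted-recovery tests quantify accuracy only at
  comparable depths.
* The simplified TMM omits precision weights and will be noisier than
  edgeR's on small counts.
* `stranded_tss_profile()` loops over TSSs and is intended for region
  sets in the thousands, not millions.
* The constraint machinery consumes pairwise alignments; producing them
  (and dating repeats) is out of scope.
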