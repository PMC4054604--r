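# tircat

Annotation of transcriptional initiation regions (TIRs) from 5'-end tag
data and chromatin-based classification of intergenic long noncoding RNAs
into enhancer-associated (**elncRNA**) and promoter-associated
(**plncRNA**) classes, with the downstream comparative statistics:
tissue specificity, neighbor-expression coupling, territory permutation
enrichment, and selective constraint against G+C-matched ancestral
repeats. A synthetic-data module generates every input with planted
ground truth, so the whole pipeline is testable offline.

Intended for computational biologists working on regulatory genomics /
epigenomics who want the individual steps of an enhancer-vs-promoter
lncRNA catalogue as tested, composable R functions rather than a
monolithic script.

## The method in brief

* **TIR calling.** Tag 5'-end positions on one strand are single-linkage
  clustered at <= 20 bp; clusters <= 400 bp apart (edge-to-edge) merge
  into a TIR; TIRs need >= 5 supporting reads and >= 1 bp overlap with a
  DNase I hypersensitive site.
* **Classification.** For each TIR, H3K4me1 and H3K4me3 coverage is
  summed in a +-1 kb window and normalised per million; the sign of
  `me1 - me3` labels the TIR enhancer-like (> 0) or promoter-like (< 0).
* **Catalogue.** TIR-linked transcripts are intragenic (>= 1 bp overlap
  with a coding gene), bidirectional (opposite-strand TIR within 1 kb of
  a coding TIR), or intergenic; intergenic noncoding transcripts with
  mature length > 200 nt become lncRNAs and inherit their TIR's class.
* **Statistics.** Tissue specificity `Ts_i = x_i / sum(x)` and `maxTs`;
  the neighbor fold difference
  `delta = (n_max - n_min) / n_min` evaluated at the reference locus's
  extreme stages (values floored at epsilon = 0.01); permutation
  enrichment with the add-one estimator `p = (1 + #[perm >= obs]) /
  (n_perm + 1)`; substitution distances (JC69 / K80 / GTR closed forms)
  relative to pooled ancestral repeats within 500 kb and +-0.05 G+C.

See `vignettes/tircat-methods.Rmd` for assumptions, parameter defaults
and design rationale.

## Worked example

```r
library(tircat)

bundle <- simulate_bundle(simulation_config(seed = 42))
bundle
#> sim_bundle: 50 planted loci ( 30 coding, 20 lncRNA ), 2342 tags

res <- run_pipeline(bundle, pipeline_params(n_perm = 200, seed = 42))
res
#> tircat pipeline: 2342 tags -> 50 TIRs -> 50 filtered -> 50 linked
#> transcripts -> 20 intergenic lncRNAs ( 10 elncRNA / 10 plncRNA )
```

All 50 planted loci are recovered as TIRs and the planted 10/10 class
split is reproduced exactly. The per-TIR classification table:

```r
head(res$classifications, 3)
#>           id me1_score me3_score      diff log2_ratio         label
#> 1: TIR_00001  487507.6   1193674 -706165.9 -1.2919099 promoter_like
#> 2: TIR_00002  792199.9   1193674 -401473.7 -0.5914713 promoter_like
#> 3: TIR_00003  457038.4   1133990 -676951.5 -1.3110186 promoter_like
```

The planted biology comes back out the other end:

```r
res$report$tissue_specificity        # elncRNAs are more tissue-restricted
#>    lnc_class  n median_max_ts
#> 1:   plncRNA 10     0.2300161
#> 2:   elncRNA 10     0.4467305

res$report$delta                     # elncRNA neighbors track their lncRNA
#> $median_a  5.064042   (elncRNA neighbor delta)
#> $median_b  0.08549982 (plncRNA neighbor delta)
#> $p         1.082509e-05

str(res$report$constraint)           # plncRNA TIRs evolve ~20% slower
#> $ elncRNA: median_relative_rate 1.06,  p 0.076   (neutral)
#> $ plncRNA: median_relative_rate 0.822, p 0.00018 (constrained)
```

`median_relative_rate` is the element substitution rate divided by the
rate of its matched ancestral repeats: ~1 means neutral evolution, 0.82
means ~20% constraint, exactly as planted (rate factor 0.8 for plncRNA
TIRs, 1.0 for elncRNA TIRs, neutral rate 0.165 subs/site).

A thin command-line wrapper is installed at
`system.file("cli", "tircat.R", package = "tircat")` with `simulate` and
`run-all` subcommands.

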