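# stasis16S

Why does 16S rRNA barely change between bacterial species whose genomes
have drifted far apart? `stasis16S` is an R package for quantifying this
evolutionary stasis and for probing its two candidate mechanisms —
horizontal transfer (HGT) of rRNA variants between lineages, and concerted
evolution (gene-conversion homogenization of the multi-copy rRNA array).
It is aimed at microbial genomicists and molecular evolution researchers
who want to reproduce the genus-scale comparison of 16S divergence against
genome-wide divergence, or to stress-test such analyses on simulated
ground truth.

## What it computes

For a set of genomes (simulated, or supplied as FASTA):

* **Genome-wide divergence** — fragment-based average nucleotide identity
  (ANI; non-overlapping 1000-bp fragments, 70/70 retention floors,
  symmetrized mean) and concatenated single-copy-ortholog ML distances
  (reciprocal-best-hit orthology; Jukes–Cantor correction
  `d = -(3/4) ln(1 - 4p/3)` for nucleotides, Poisson correction
  `d = -(19/20) ln(1 - 20p/19)` for proteins).
* **Transfer flags** — a species pair is a candidate rRNA transfer when
  its 16S representatives exceed 99.9% identity while ANI is below the
  ~95% species boundary.
* **Rate curves** — zero-intercept linear (`y = bx`), second-order
  polynomial (`y = b1 x + b2 x²`) and logarithmic (`y = a ln(1 + x/s)`)
  fits of 16S divergence against genomic distance, with nested F-test
  selection; a selected quadratic with `b2 < 0` is the stasis signature.
* **Intragenomic variant mixtures** — a catalog of well-separated 16S
  variants (mismatches + gap openings ≥ 2), per-genome composition
  profiles (e.g. 5:2 of variants A:B), two-variant mixture spectra, a
  Fitch-parsimony permutation test for phylogenetic randomness of variant
  possession, and an exact hypergeometric test for enrichment against
  metadata labels.
* **A forward genus simulator** — Yule tree, Jukes–Cantor substitution,
  a slower multi-copy rRNA array, Gillespie-sampled gene conversion and
  inter-lineage rRNA transfer with a ground-truth event log, plus a
  vertebrate control mode (no HGT; slow 18S analog + ~10× faster
  mitochondrial 16S analog). Every pipeline stage is verifiable against
  planted truth without downloading anything.

The alignment kernel (affine-gap global alignment with deterministic
tie-breaking, exactly symmetric identity, `N` never matches) is
implemented in C++ and cross-checked in the test suite against an
independent dynamic-programming oracle and against Biostrings.

## Worked example

Simulate a 12-species genus, plant one recent whole-array rRNA transfer
into its most genome-divergent species pair, and scan for it:

```r
library(stasis16S)

p <- simParams(nSpecies = 12L, treeDepth = 0.15, nGenes = 4L, geneLen = 500L,
               rrnaLen = 800L, rrnaCopyNumber = 4L, rrnaRateFactor = 0.15,
               conversionRate = 1)
tr  <- simulateTree(12, treeDepth = 0.15, seed = 42)
sim <- simulateGenus(tr, p, seed = 43)
sim
#> GenusSimulation with 12 genomes
#>   tree depth: 0.15 substitutions/site
#>   events: conversion=3

ani <- aniMatrix(simGenomes(sim), fragLen = 500L)
far <- which(ani == min(ani), arr.ind = TRUE)[1, ]
sim <- plantHgtEvents(sim, donors = rownames(ani)[far[1]],
                      recipients = colnames(ani)[far[2]])

ml    <- concatMlDistance(scoTableFromSimulation(sim))
pairs <- buildPairTable(simGenomes(sim), ani, ml)
det   <- detectHgtPairs(pairs)
det$flagged[, c("species_a", "species_b", "ani", "rrna_identity")]
#>       species_a species_b      ani rrna_identity
#> s0015      s001      s007 74.06248           100

summarizeGenus("DemoGenus", simGenomes(sim), det$pairs)
#>       genus n_species n_hgt_pairs copy_number_median copy_number_q1 copy_number_q3 n_sco
#> 1 DemoGenus        12           1                  4              4              4    NA

fit <- selectModel(fitLinearOrigin(pairs$ml_distance, pairs$rrna_divergence),
                   fitQuadraticOrigin(pairs$ml_distance, pairs$rrna_divergence))
fit
#> RateFit: quadratic_origin
#>   coefficients: b1=40.596, b2=-97.516
#>   rss=78.1893 on n=66 points; F=20.01, p=3.224e-05, selected=TRUE
```

Reading the output: the planted transfer is recovered as a pair sharing an
identical 16S (100% identity) despite genomes only 74.1% identical — far
beyond the ~95% species boundary — and the genus summary counts it. The
selected quadratic with a negative second-order coefficient shows 16S
divergence flattening with genomic distance: the stasis signature.

`runEndToEnd()` orchestrates the same stages (plus the variant-mixture
analysis) from a single config and writes TSV/JSON reports with a
reproducibility manifest; `inst/scripts/run_pipeline.R` is a thin
command-line wrapper around it. The methods vignette
(`vignettes/methods.Rmd`) documents every model, parameter and design
decision.

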