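---
title: "Models and methods behind stasis16S"
author: "stasis16S authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stasis16S}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

16S rRNA is the classical bacterial identification marker, yet within many
genera its divergence between species is strikingly small compared to
genome-wide divergence, and well-separated species pairs are sometimes found
sharing an essentially identical 16S variant. Two mechanisms can produce and
maintain such stasis: horizontal transfer (HGT) of rRNA variants between
lineages, and concerted evolution — intragenomic homogenization of the
multi-copy rRNA array by gene conversion. `stasis16S` implements the
comparative analyses that expose these signals (16S identity versus
genome-wide divergence, rate-curve model selection, intragenomic
variant-mixture profiling) together with a forward simulator that provides
ground truth for every stage.

# The simulator

`simulateGenus()` evolves a genus along an ultrametric species tree
(`simulateTree()` draws a Yule tree and rescales all root-to-tip paths to
`treeDepth`, measured in expected marker substitutions per site — so "time"
and marker branch length coincide).

* **Substitution.** Every site is hit by a Poisson process at rate 1
  (markers) or `rrnaRateFactor` (each rRNA copy, independently); each hit
  replaces the base with one of the other three, applied sequentially so
  multiple hits compose. This is exactly the Jukes–Cantor process: the
  expected proportion of differing sites after branch length $d$ is
  $p = \tfrac34\!\left(1 - e^{-4d/3}\right)$, which the test suite verifies
  against simulation. Jukes–Cantor was chosen because every downstream
  statistic is identity-based; richer substitution models would change
  nothing structural.
* **Gene conversion.** At rate `conversionRate` $\gamma$ per copy per unit
  branch length, a uniformly chosen copy of a uniformly chosen lineage is
  overwritten by a uniformly chosen sister copy of the same genome (whole
  copy replacement — the homogenization mode relevant for variant-level
  dynamics).
* **Horizontal transfer.** At rate `hgtRate` $\eta$ per coexisting lineage
  pair per unit time, a random donor's *majority variant* (the consensus
  under `selectRepresentative()` rules) replaces the recipient's copies —
  all of them (`all_copies`) or a random subset (`k_copies`). Whether real
  rRNA transfers move whole operons or fragments is not settled; both
  scopes are simulated and neither is claimed as the true mechanism.
* **Event sampling** is Gillespie-style between speciation times: no hidden
  time discretization exists, and every event is appended to a ground-truth
  log (`eventLog()`) used by the recovery tests.
* **Determinism.** One seed governs every draw; identical parameters and
  seed give byte-identical genomes, logs and report files.

`plantHgtEvents()` additionally applies transfers *at the present* between
named tips. Recovery experiments use it because a "recent transfer between
well-separated species" — the situation behind the dark crosses of the
identity-versus-ANI scatter — needs donor and recipient to be identifiable
tips, which mid-branch stochastic events do not guarantee.

`simulateVertebrateMode()` is the no-HGT control: two single-copy loci, a
slow nuclear "18S analog" (rate factor `r18`, default 0.1) and a fast
"mitochondrial 16S analog" (default $10\times$ `r18`), with transfer and
conversion forcibly zero — requesting either is an error, because their
absence is what makes vertebrates the control group.

## What the generator does and does not emulate

It emulates: clock-like divergence of a genus, a multi-copy rRNA array with
decelerated substitution, concerted evolution, recent inter-lineage rRNA
transfer, and ancestral intragenomic polymorphism (`plantedVariantArray()`).
It does **not** emulate genome rearrangement, gene gain/loss, intergenic
DNA, codon structure, rate heterogeneity across sites, selection, or
recombination outside the rRNA array. Passing tests therefore demonstrate
that the *pipeline* recovers planted signals under idealized clock-like
evolution; they do not certify performance on real assemblies with
contamination, misassembly or annotation errors.

# Alignment and distance kernels

All identity values flow through one affine-gap global aligner
(Needleman–Wunsch/Gotoh, implemented in C++):

* Default scoring: match $+1$, mismatch $-1$, gap open $-2$, gap extend
  $-0.5$; a length-$L$ gap costs $-2 - 0.5L$. Conventional and
  configurable.
* **Tie-breaking** is deterministic (diagonal preferred over gap-in-`b`
  preferred over gap-in-`a`), and arguments are canonicalized
  lexicographically before alignment so that equal-score alignments cannot
  make column counts asymmetric: identity is *exactly* symmetric in its
  inputs.
* **`N` never matches anything**, including another `N` — conservative for
  thresholds in the 99.9% range.
* **Identity denominator includes gap columns** (each column once):
  $\mathrm{id} = 100\,m/(m + mm + g)$. The variant-catalog metric counts
  mismatches + gap *openings*, so a contiguous indel is one event. These
  definitions penalize indels, consistent with treating them as single
  evolutionary events.
* An optional diagonal **band** accelerates alignment of same-length
  high-identity pairs (simulator output has no indels, so a modest band is
  exact; the tests assert banded = full DP on such pairs). The default is
  always the full dynamic program.
* Closed-form ML corrections: Jukes–Cantor
  $d = -\tfrac34\ln(1 - 4p/3)$ (domain $p < 3/4$) and the Poisson
  amino-acid estimator $d = -\tfrac{19}{20}\ln(1 - 20p/19)$ (domain
  $p < 19/20$). Out-of-domain proportions raise saturation errors; the
  distance-matrix builder reports such pairs as `NA` with a `"saturated"`
  attribute rather than clamping. The Poisson form is used for "ML protein
  distance" because it is the closed-form ML estimator of the equal-rate
  amino-acid model and hence exactly testable; no substitution matrix is
  assumed.

# Genome-scale divergence

`computeANI()` follows the classical fragment formulation the ~95% species
boundary was calibrated against: non-overlapping 1000-bp query windows,
best placement on the subject (exact 9-mer probes every 20 bp vote for a
diagonal; two concordant votes open a seeded window, otherwise the fragment
is aligned against the whole subject), retention floors of 70% identity and
70% coverage, and the mean retained identity per direction plus a
symmetrized mean. All parameters are exposed.

`findScoRbh()` implements strict complete single-copy orthology:
reciprocal best hits under the alignment score, retained only for families
forming a complete one-per-species clique. No tree reconciliation is
attempted — at desk scale, and with `scoTableFromSimulation()` providing
known orthology for simulated data, the two paths must and do agree
(tested at moderate depth). `concatMlDistance()` aligns each family,
concatenates aligned columns, computes $p$ over non-gap columns (gap
exclusion is standard for distance estimation and intentionally differs
from the identity denominator) and applies the ML correction. Its default
scoring uses stiff gap penalties (open $-8$, extend $-2$): with permissive
penalties the optimizer converts runs of mismatches into spurious gaps at
high divergence, deflating $p$ and biasing distances ~10% short on clock
simulations; stiff penalties keep gaps for genuine indels and make the
estimator additive-in-expectation (regression slope ~1 against true path
lengths — a tested invariant). A related subtlety constrains how rank
recovery can be tested: on an ultrametric tree every pair sharing an MRCA
has *exactly* the same true path length, and these ties cap the raw
Spearman correlation against true distances (at ~0.90 for a 30-species
Yule tree) for any estimator, so the suite checks rank recovery on
tie-group means instead.

# The stasis scan

Each species is represented by the **majority variant** of its intact rRNA
copies (intact: length at least 80% of the expected copy length, no `NN`
runs; ties break by length then lexicographically). Majority
representation is robust to the deletion-affected, possibly pseudogenized
copies that dominate apparent intragenomic variability in real assemblies.
A species pair is flagged as a candidate transfer when 16S identity
exceeds 99.9% **and** ANI lies below 95% — "evolutionarily well separated"
is operationalized as the conventional ANI species boundary; both
thresholds are parameters. Flag monotonicity (raising the identity
threshold or lowering the separation threshold never adds flags) is a
tested invariant. `intergenusScan()` applies the same conjunction across
genera, evaluating ANI only for pairs that already share a near-identical
16S (the conjunction makes this lazy evaluation exact).

# Rate-curve models

Pairwise points (one per species pair) are fitted with

* `fitLinearOrigin()`: $y = bx$ through the origin — the neutral
  expectation of linear mutation accumulation; $b = \sum xy / \sum x^2$.
* `fitQuadraticOrigin()`: $y = b_1 x + b_2 x^2$; a negative $b_2$ is the
  stasis signature (divergence flattens with distance).
* `fitLogarithmic()`: $y = a \ln(1 + x/s)$ with fixed scale $s$, linear in
  $a$ and hence closed-form. For the mitochondrial-analog fits the scale is
  set to the Jukes–Cantor saturation scale of the locus,
  $s = 3/(4 \cdot \text{rate})$; the generic default $s = 0.1$ remains for
  exploratory use.
* `selectModel()`: nested F-test,
  $F = (\mathrm{RSS_{lin}} - \mathrm{RSS_{quad}})/(\mathrm{RSS_{quad}}/(n-2))$,
  quadratic selected iff $p < 0.05$. "Fits significantly better" implies a
  test; the F-test (not AIC) keeps the decision calibrated, which the
  suite checks on linear-truth data. A quadratic that interpolates
  perfectly is selected only if the linear fit does not also interpolate.
* `slopeRatio()`: ratio of two origin slopes with a delta-method standard
  error, used to recover the planted mitochondrial/nuclear rate ratio.

Pairwise points share ancestry and are not independent; the fits reproduce
the field's practice and should be read descriptively. (Phylogenetically
corrected regression is out of scope.) The y-axis is raw percent
divergence by default; corrected distances can be supplied instead.

# Intragenomic variant analysis

`buildCatalog()` dereplicates intact copies across genomes and clusters
greedily in order of descending abundance (lexicographic tie-break): a
sequence founds a new reference variant iff it differs from every founder
by at least `minSep` = 2 mismatches + gap openings — so a single
sequencing/assembly error cannot found a variant. Labels `A`, `B`, `C`,
... follow founding order; the catalog is invariant to genome input order
(tested). `assignProfiles()` assigns every intact copy to its nearest
variant within `assignRadius` = 1, ties to the earlier label, the rest
unassigned; per genome, assigned + unassigned equals the intact copy count
(a tested conservation law). `mixtureSpectrum()` histograms two-variant
compositions (7:0, 6:1, ..., 0:7 for a seven-copy array).

`phyloRandomnessTest()` asks whether possession of the dominant variant
clusters on the phylogeny: the statistic is the Fitch parsimony score of
the dominant-variant character (exact, fast, assumption-light), the null
is tip-label permutation. Because the parsimony score is a small integer,
permutation ties are frequent and the classical
$(1 + \#\{\text{perm} \le \text{obs}\})/(1 + n)$ value is super-uniform
(conservative) — it demonstrably fails a Kolmogorov–Smirnov uniformity
check under the null. The default `p` therefore breaks ties uniformly at
random, which is exactly calibrated under exchangeability; the
conservative value is returned alongside (`pConservative`). A low p means
clustering; random scatter across the tree — the pattern expected under
rampant transfer or concerted turnover — gives a non-significant p.

`labelEnrichment()` tests association between variant enrichment (at
least 2 copies of the focal variant by default, mirroring the
single-copy-in-reference-strain baseline) and a metadata label (the
serotype-analog situation) with the one-sided hypergeometric tail
(`phyper`), verified in the tests against direct `dhyper` enumeration.

# Study conditions used by the verification experiments

The acceptance-style tests and `scripts/acceptance.R` run these
experiments (sizes chosen as realistic desk-scale analogs; each is a
package design choice):

* **ANI calibration**: 20 pairs of 10-kb genomes mutated at a planted JC
  distance of 0.05/site; the JC-expected identity is
  $100(1 - \tfrac34(1 - e^{-4\cdot 0.05/3})) \approx 95.2\%$ — the species
  boundary region.
* **Transfer recovery**: 30 species, depth 0.15, 4 rRNA copies of 1550 bp,
  `rrnaRateFactor` 0.15. At the ANI-95 boundary (genome distance ~0.052)
  the expected 16S divergence is ~0.78%, i.e. ~12 expected differences —
  so the Poisson probability that a *natural* well-separated pair shows
  $\le 1$ difference (identity > 99.9%) is ~$7\times10^{-5}$, and false
  positives are structurally excluded rather than merely unlikely. A
  smaller rate factor (e.g. 0.05, ~4 expected differences) satisfies a
  naive ">0.1% divergence" reading but lets Poisson noise through. Five
  whole-array transfers are planted between *disjoint* sub-93%-ANI pairs
  (disjoint so no transfer overwrites another's recipient); recall must be
  1 and ten matched no-transfer replicates must yield zero flaggable
  pairs. Flagged pairs beyond the planted five do occur — recipients also
  match close relatives of their donors — and are correct detections of
  shared variants, not false positives.
* **Concave rate curves**: 15 species, depth 0.5, `rrnaRateFactor` 0.3,
  `hgtRate` 1 — roughly one transfer per lineage pair per unit time keeps
  distant pairs' 16S similar while close pairs diverge normally, so
  divergence flattens with distance and the quadratic model with
  $b_2 < 0$ should win; 100 replicates, against 100 linear-truth
  replicates for type-I control.
* **Homogenization**: conversion at $100\times$ the per-copy substitution
  rate (`rrnaRateFactor` $\times$ `rrnaLen` per unit branch length — the
  per-copy reading is the dimensionally consistent one, since conversion
  is also a per-copy rate; the per-site reading would predict ~3%
  equilibrium copy divergence, contradicting homogenization). Median
  intragenomic copy identity must stay at or above 99.9%.
* **Vertebrate control**: 40 species at depth 0.3 with a planted
  $10\times$ rate ratio; saturation attenuates the recovered slope ratio
  to ~6–8, within the expected [5, 20] window, and the logarithmic fit
  must beat the linear one for the mitochondrial analog.
* **Variant mixtures**: 60 isolates on a *star* phylogeny of depth 0.3
  with a planted three-variant six-copy array (2,2,2; consecutive variants
  6 differences apart) and conversion rate 15. The star shape models an
  intraspecific radiation with private isolate histories; on a Yule genus
  tree the long shared early branches let conversion drift variant
  frequencies before the radiation, so whole variants go extinct or lose
  all pure genomes — a tree-shape property, not a rate choice. The rRNA
  rate factor is $10^{-9}$ (the domain requires it positive), isolating
  conversion dynamics: the catalog must contain exactly the three planted
  variants, profiles must conserve copy counts, and pure-A/B/C plus mixed
  genomes must all be detected simultaneously.
* **Determinism**: a 20-species demo pipeline run, executed twice with one
  seed, must be byte-identical file by file.

# Known limitations

* The aligner is nucleotide-oriented; in amino-acid mode all residues
  score match/mismatch uniformly and the letter `N` (asparagine) never
  matches — adequate for the equal-rate Poisson distance, wrong for
  scoring-matrix work, which is out of scope.
* Real Table-style per-genus counts require the original bulk genome sets;
  the package reproduces the *properties* of the analysis on synthetic
  ground truth and ingests user-supplied FASTA for real-mode runs.
* Fragment ANI is exact but not sketch-accelerated; genome pairs beyond a
  few hundred kb per genome will be slow (Mash-style ANI is a non-goal).
* The pairwise regression points are non-independent (shared ancestry);
  inferential statistics on them are descriptive.
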