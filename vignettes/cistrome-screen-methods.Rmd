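---
title: "Methods: scoring, predicting and stress-testing binding-site essentiality screens"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: binding-site essentiality screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. Everything quantitative stated here is computed by
the test suite or by `scripts/acceptance.R`; nothing is quoted from
elsewhere.

# The selection model

A pooled knockout screen measures, for every guide, an abundance at
day 0 and at an endpoint several weeks later. If a disrupted element
changes cellular fitness by a per-generation selection coefficient
`beta`, the expected abundance follows exponential growth,

```
mu_end = mu_0 * 2^(beta * G)
```

with `G` the effective number of population doublings between the two
time points. The per-site estimator inverts this link: the beta-score is
the trimmed mean (10% trim by default) of the site's guide log2 fold
changes divided by `G`. The trimmed mean keeps the "beta is an LFC-like
quantity" semantics while shrugging off the occasional outlier guide
(cloning dropouts, off-target kills); the full maximum-likelihood
treatment used by dedicated screen callers is deliberately out of scope
— on synthetic screens the trimmed mean already tracks truth with
Spearman ~0.95 at 16 guides/site (acceptance suite), so the simpler,
fully specified estimator is preferred.

`G` is configurable (default 10 doublings, roughly a 4-week screen of a
fast-growing line). No conclusion in the package depends on its value
beyond an overall scale: ranks, signs, p-values and FDRs are invariant
to it.

## The permutation null and its calibration

P-values come from resampling site-sized guide sets from the AAVS1
safe-harbor negative controls and recomputing the trimmed-mean statistic
(two-sided, with the +1 small-sample correction). This choice makes the
null distribution inherit every nuisance property of real guides —
count noise, normalization error, dispersion — without modeling them.
Two practical notes:

* The null's accuracy is limited by the control set's sampling noise.
  With a few hundred controls the estimated null spread can be several
  percent off, which moves the nominal 5% tail by 1-3 points. The
  calibration checks therefore use screens with 2,000 control guides,
  where the estimator itself — not control-set luck — is what is being
  measured. The test asserts the null fraction of `p < 0.05` lands in
  0.05 +/- 0.02 at 1,000 sites.
* Sites of equal guide count share one null sample for speed; this
  introduces weak dependence between their p-values but no bias, and
  4,000 permutations keep the shared-quantile noise below the binomial
  noise of the assertion.

The alpha-RRA score is atomic: a site with no guide below the
`alpha = 0.05` rank cutoff scores exactly 1, and a large fraction of
null sites do. Permutation p-values at such atoms are computed with
randomized tie-breaking (drawn inside the seeded stream), the standard
construction that restores exact null uniformity for a discrete
statistic; the score itself, which is what rankings use, is untouched
and matches the closed-form Beta order-statistic computation to 1e-10.

## Normalization and copy number

Size factors are median ratios to the first day-0 sample over guides
with nonzero counts everywhere. When a screen has a large genuinely
depleted fraction — strong selection plus copy-number-driven multi-cut
toxicity can put a third of guides well below their day-0 abundance —
the global median absorbs part of that signal and shifts every LFC.
`scoreScreen()` therefore computes the medians over the AAVS1 controls
when they are present (`normalizeCounts(controlGuides=)`); the global
median remains the default of the low-level function.

The copy-number correction fits `beta ~ CN` by least squares over all
sites and subtracts the fitted trend re-anchored at the diploid state.
A linear trend is the simplest monotone removal consistent with an
additive per-extra-copy toxicity; on synthetic screens with the default
confounder (-0.1 per extra copy) it takes |cor(beta, CN)| from ~0.97 to
~0 while leaving an unconfounded screen untouched (max adjustment
< 0.02). When every site is diploid the adjustment is the identity by
construction — no degenerate fit is attempted.

# What the generator emulates — and what it does not

`simulateGenome()` draws chromosomes, gene TSSs with gene-level
selection scores, binding sites with summits and selection classes
(strong-signal and near-essential-gene sites map to FOXA1; constitutive
and cell-specific sites to CTCF), TAD boundaries, loop anchors with a
head-to-head orientation flag, and a copy-number tiling. Counts are
negative binomial (`variance = mu + dispersion * mu^2`) around
log-normally spread library-representation means — the standard model
family for pooled screen counts. Defaults the source screens do not
pin down were chosen once as field-realistic and are stated here:
sequencing depth 500 expected reads/guide, dispersion 0.2, 2 replicates
per arm, representation spread sdlog 0.3, positive-control selection
Normal(-0.5, 0.1) per generation. Ground-truth selection gives
essential sites Normal(-0.6, 0.1) and non-essential sites a small
near-neutral Normal(0, 0.05) — real elements are rarely exactly
neutral, and that residual variation is what a well-powered screen
should track (it is also what makes a rank correlation against truth
meaningful rather than tie-dominated).

What passing tests on this generator *show*: the estimators are
unbiased and calibrated under the stated noise model, the correction
removes the stated confounder, the feature ranking and classifier
recover planted structure, the enrichment test flags planted
enrichment. What they *cannot* show: robustness to guide-efficiency
heterogeneity, chromatin-dependent Cas9 access, sequencing batch
effects, or compositional distortions of deep selection — none of which
the generator models. Conclusions about real screens need the real
controls those effects demand.

Feature tables are Gaussian on a log-signal scale with essential-site
mean shifts. The default shift ordering (DNase 1.0 > nearby-gene
essentiality 0.9 > nearby-gene expression 0.8 > H3K27ac 0.6 > ER 0.5 >
H3K4me2 0.4 > FOXA1 binding 0.2) encodes the qualitative structure the
analyses are meant to detect: open chromatin and nearby-gene properties
most informative, the targeted factor's own binding strength least.
Recovery of the DNase > H3K27ac > FOXA1 order is asserted across seeds
at 2,000 sites — at a few hundred sites the top-5% group is ~15-30
sites and adjacent shifts are not statistically separable, which is a
fact about power, not about the ranking code.

# The predictor

Labels follow the screen: essential = negative-selection rank below a
threshold (300 in a ~6,000-site library; scaled as 5% of sites in
synthetic runs, an explicitly documented deviation tied to library
size); non-essential = `p > 0.5` and `|LFC| < 0.1`. The larger class is
downsampled (seeded, uniform) to a 0.85-1.1 ratio — balancing changes
membership, never labels.

The classifier is an RBF-kernel SVM on standardized features (linear
kernel by flag); decision values are used as scores, oriented so higher
means more essential. The GA wrapper holds out a fixed, seeded 70/30
validation split, scores feature subsets by validation AUROC, carries a
20% elite, and mutates rank-weighted parents by adding/removing/swapping
exactly one feature. Population 30 and 50 generations are the package
defaults; the acceptance benchmark uses 20 x 30 — ample for a 13-feature
space whose full enumeration is 8,191 subsets — and recovers all three
planted informative features in >= 9/10 seeds. ROC and PR curves are
assembled by threshold sweep with tie grouping; the trapezoid AUC is
tested against the Mann-Whitney identity `U / (n+ * n-)` on every kind
of score set, and cross-checked against an independent ROC
implementation. The model benchmark labels sites by generative truth at
50% prevalence (balanced by construction); label-rule recovery from
screen output is tested separately, so the benchmark isolates the
classifier.

Cross-validation is stratified 5-fold with pooled out-of-fold scores;
at 2,000 sites with the default effect ordering the CV AUC (~0.87)
clears both the 0.75 floor and the best single feature (~0.76),
mirroring the qualitative claim that the joint model beats any single
epigenomic signal.

# SNP enrichment

SNP positions are treated as 1-based on input and converted internally.
The assignment hierarchy is deterministic (DNase peak, then TF peak,
then a 150-bp window centered on the SNP; nearest peak midpoint breaks
within-tier ties), so permuting peak input order cannot change
assignments. The per-trait 2x2 test is Pearson chi-squared without
continuity correction (flag to enable), switching to Fisher's exact
test when an expected cell drops below 1; both paths are oracle-tested
and agree within an order of magnitude at the switch boundary. The
significance line is BH-FDR < 20% across traits, intentionally distinct
from the screen's site-level FDR < 0.25. The default background is all
assigned enhancers of the relevant factor class; fold enrichment is the
observed in-essential rate over the background essential rate, so the
background against itself is exactly 1.

# Numerical choices and degenerate inputs

* Pseudocount 0.5 after size-factor scaling keeps every LFC finite and
  is negligible at depth 500.
* Guide-selection ties (equidistant cuts) break by lower coordinate,
  then plus strand; pgRNA pairs rank by total flanking distance with
  the same lexicographic tie-break. `neg_rank` uses first-occurrence
  tie-breaking so it is always a permutation.
* Constant features: the SVM drops zero-variance columns (they cannot
  be standardized); a feature constant across all sites gets `p = 1`
  and a flag in the ranking rather than an error.
* Empty confusion-matrix cells in the error analysis are skipped with a
  notice; a class empty after labeling raises an error naming the rule
  that produced it.
* All intervals are 1-based closed in memory (GRanges) and 0-based
  half-open in BED files; readers and writers invert each other
  exactly, and the round trip is tested.
* Sub-seeds are derived per operation from (master seed, operation
  name), so each stage is individually reproducible and stages do not
  share streams.

# Problem sizes

The test and acceptance runs use 1,000-site screens at 16 guides/site
for estimator recovery and calibration, 2,000 sites for feature-ranking
and model benchmarks, 600 sites for the GA recovery loop, 500 sites and
500 SNPs/trait for enrichment recovery, and a 200-site demo pipeline.
These sizes were chosen so each assertion has comfortable statistical
margin (see the power notes above) while a full run stays in the
minutes range on a single CPU.

# Known limitations

* The beta estimator is a trimmed mean, not a joint MLE across
  conditions; multi-screen designs are scored one screen at a time.
* Guide efficiency and specificity are pluggable inputs; no sequence
  model predicts them, and no off-target alignment search is performed.
* The SNP module does no linkage-disequilibrium expansion; each SNP is
  tested where it sits.
* The generator emits TADs/anchors as intervals directly and sequences
  only on request — there is no Hi-C or FASTA-level realism.
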