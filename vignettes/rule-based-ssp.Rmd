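---
title: "Single-sample multiclass prediction with gene-pair rules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample multiclass prediction with gene-pair rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sspRules)
```

# The problem

Multiclass prediction from tumor transcriptomes — calling a molecular
subtype for a new sample — is usually done with classifiers that operate on
cohort-normalized, row-centered expression values. Such classifiers see a
sample only *relative to the batch it arrives in*: the cohort's subtype
composition, platform, and preprocessing all leak into the prediction. A
single-sample predictor (SSP) instead uses only the measurements within one
sample, so it is invariant to cohort composition and, ideally, robust to
platform shifts and tumor purity.

The package implements and compares five predictor families on a common
data model (`ExpressionCohort`, a `SummarizedExperiment` of raw-scale
genes-by-samples values with class/platform/dataset metadata), plus a
synthetic cohort generator with recorded ground truth so that every claimed
behavior is testable without external downloads.

The load-bearing primitive for three of the five families is the **gene-pair
rule**: the binary feature `expr(A) > expr(B)` evaluated within one sample.
Rule values are invariant under any strictly increasing per-sample transform
of expression — this, not any particular classifier, is what makes the
rule-based methods SSPs. Exact expression ties evaluate to FALSE (strict
inequality), a deterministic convention asserted in the tests.

# The five predictors

## Nearest centroids (`trainCentroid`, modes `raw` and `centered`)

Per class, genes pass a moderated-t gate (limma empirical-Bayes, p < 0.05)
and a direction-free subtype-vs-rest AUC gate (> 0.6), are ranked by mean
log fold change, and the top `m` up- and downregulated genes per class are
pooled into a deduplicated union. Class centroids are mean expression
profiles over the union; a sample is scored by Pearson correlation against
each centroid and assigned to the nearest.

* `raw` mode averages uncentered values — the "single-sample centroid".
  Prediction of a sample is invariant to positive affine rescaling of that
  sample (the Pearson contract) but, deliberately, not to non-linear
  monotone transforms: the correlation is computed on the value scale.
* `centered` mode averages per-gene mean-centered training values and
  stores the training row means; new samples are centered with those stored
  means only, never with their own batch. This keeps even the conventional
  centroid honest as a per-sample predictor at application time.

The AUC gate is applied direction-free (`max(AUC, 1-AUC) > 0.6`) because a
downregulated marker carries the same discriminative information with an
oriented AUC below 0.5.

## Multiclass k-TSP (`trainKTSP`)

One one-vs-rest binary voter per class. Each voter selects the top
`nGenesPerDirection` up- and downregulated genes by Wilcoxon rank-sum
statistic, scores every candidate pair by the TSP score
`delta = |P(rule | class) - P(rule | rest)|` with the mean within-sample
rank difference (`gamma`) breaking delta ties, and greedily keeps top pairs
whose genes are unused so far (classic disjointness). The number of rules k
is chosen by **variance optimization**: over `kRange`, the k maximizing the
between-group separation of the training vote sums divided by their pooled
within-group standard deviation (ties toward smaller k). The literature
this method descends from names the criterion without printing it; the
definition above is this package's reproducible reading. A sample's score
per class is the fraction of TRUE rules; the highest vote fraction wins.

Variants, each behind a config flag: `fixedK` (forced rule count),
`pivotGenes` (pairs between pool genes and all remaining genes — a
non-differential gene can act as the pivot point of a highly informative
rule), `one_vs_one` gene selection and rule scoring, and `platformWise`
selection/scoring. Both the one-vs-one and platform-wise aggregations use
the *worst case* (minimum) of the per-comparison signed deltas, so a rule
scores highly only if it discriminates against every opposing class / on
every platform. These aggregations are tool definitions: the variants are
named in the k-TSP literature without formulas, and they reduce exactly to
the default when C = 2 or one platform is present (asserted in tests).

Vote fractions live on the grid 0, 1/k, ..., 1, so **tied top scores are a
real phenomenon** at small k. Ties are resolved to the lexicographically
first class and always flagged. The tie-rate sweep (`tieSweep`) reproduces
the decline of tie prevalence with growing k.

## Naive Bayes over rules (`trainNBRules`)

All gene pairs are enumerated (above `candidateGeneCap = 300` genes the
input is first reduced by Wilcoxon statistics — exhaustive enumeration is
quadratic and 300 genes already yield ~45k rules). Rules are ranked per
class by delta; the per-class rule count k — constrained to be the *same
for every class* — is chosen at the peak mean accuracy of a stratified
20-fold cross-validation over k in 1..50, smallest k on ties. The final
model is a multiclass Bernoulli Naive Bayes over the selected rules with
class-proportion priors and Laplace smoothing (alpha = 1, configurable;
the upstream method's smoothing constant is not published).

Optional `datasetWeights` average the per-dataset signed deltas with
user weights (e.g. inversely proportional to dataset size), damping rules
that discriminate only in a dominant dataset. The weighting formula of the
original method is unpublished; the weighted-average delta is this
package's interpretation and is isolated behind the config.

NB posteriors are near 0/1 even for out-of-distribution samples — the
conditional independence assumption multiplies dozens of extreme Bernoulli
terms — so the score is a poor confidence measure: the tests assert that NB
margins exceed k-TSP margins on purity-degraded samples even as accuracy
drops.

## Rule-based Random Forest (`trainRFRules`)

The three-stage pipeline, with forests fitted by `ranger`:

1. **Gene selection.** On within-sample-ranked data, one all-classes
   probability-free forest plus one one-vs-rest forest per class; top
   `genesPerModel` genes per model by impurity importance, deduplicated
   union. The one-vs-rest supplementation exists because markers of small
   classes rarely reach the top of the all-classes ranking.
2. **Rule selection.** All pairs of the union are binarized and the same
   set of forests is retrained on the rules, giving per-rule importances
   per model.
3. **Diversification + final model.** Within each model's importance
   ranking, at most `geneRepetition` (default 1) rules per gene are kept,
   avoiding many rules sharing one informative partner gene; the top
   `rulesPerModel` filtered rules per model train a final probability
   forest (mtry = sqrt(#rules), node size 1, 5000 trees by default,
   in-bag membership stored per tree).

Selection forests use 5000 trees, node size 1, mtry = 10% of features and
impurity importance by default. Because each tree's bootstrap leaves out
~1/e ≈ 37% of samples, each sample is out-of-bag for ~1850 of 5000 trees;
the acceptance script recomputes both constants by direct simulation. The
stored in-bag bookkeeping supports:

* **OOB scores/accuracy** — per-sample class probabilities averaged over
  the trees where the sample was out-of-bag;
* **proximity extraction** (`extractProximity`) — the fraction of jointly
  OOB trees in which two samples share a terminal node (diagonal 1, NA for
  pairs never jointly OOB), useful for spotting incohesive reference
  labels;
* **shadow pruning** (`borutaPrune`) — the package's own implementation of
  the shadow-feature algorithm: each iteration appends per-column permuted
  copies of the rules, refits a forest, and counts rules whose importance
  beats the best shadow; a two-sided binomial test (alpha = 0.01, up to 50
  iterations, 200-500 trees per iteration) labels rules
  confirmed/tentative/rejected and the final forest is rebuilt without the
  rejected ones;
* **kNN rule imputation** (`imputeMissingRules`) — forests cannot handle
  absent features, so the binary training matrix is retained in the model;
  rules unevaluable in a new sample (missing genes) are filled with the
  modal value of the k = 5 most similar training samples, similarity being
  the Hamming agreement over the evaluable rules only (rules are imputed,
  never genes). Prediction refuses samples with more than 50% unevaluable
  rules.

Forest probability averaging over thousands of trees makes tied top scores
practically impossible; the tests assert zero ties over 1000 predictions,
documented as a probabilistic rather than structural guarantee.

# The synthetic cohort generator

`simulateCohort` draws, in order, on the natural-log abundance scale:
baseline gene means Uniform(1, 7); class profiles shifting each class's
informative genes by ±`effectSize` (half up, half down, geometrically
decaying by `effectDecay` to emulate the rank-ordered effect-size continuum
of real marker lists); a stromal/immune profile shifting a designated gene
set by `stromalEffectSize`; per-sample Gaussian noise (`noiseSD`); purity
mixing `x = p * exp(tumor) + (1-p) * exp(stroma)` with
purity ~ Beta(`purityAlpha`, `purityBeta`) — mixing is done on the
anti-logged scale because dilution is additive in transcript abundance,
not in log space; and per-platform distortion
`y = x^compression * exp(offset_g)` — a power-law dynamic-range compression
(arrays compress; exponents around 0.5-0.7 match reported cross-platform
correlations of 0.6-0.8) plus per-gene lognormal offsets (probe effects).
The emitted matrix is log2(y + 1).

Default study conditions: 5 classes, 300 genes, 20 informative genes per
class, effect 2 against noise 0.5 (strong subtype markers), purity fixed
at 1, one undistorted platform, 20 samples per class. Purity, platform
distortion, class-specific purity distributions (`purityAlpha`/`purityBeta`
as per-class vectors, for infiltrated tumor categories) and a stromal
profile overlapping one class's program (`stromalOverlapClass`) are opted
into per scenario.

Gene-level and sample-level draws flow through separate seed streams, with
one deterministic stream per sample, so regenerating a test set
(`sampleSeed`) keeps the gene universe fixed and growing a cohort never
perturbs existing samples. `injectPlatformSpecificPairs` post-hoc rewrites
chosen pairs to be class-discriminative on one platform but constant on
another — the crossover never happens there — recording the pairs in the
ground truth for sensitivity checks of the per-rule platform diagnostics
(`platformSpecificity`: per-platform folded AUC of the rule value against
class membership plus a constancy fraction; flag thresholds 0.7 / 0.55 /
0.95 are tool defaults, configurable).

What the generator does **not** emulate: read counts and library-size
effects (it targets the summarized matrix level the predictors consume),
probe sequences, correlated gene modules beyond the class/stromal programs,
label noise, and non-monotone platform effects. Passing tests therefore
demonstrate the *mechanisms* — purity robustness of within-sample ratios,
platform-specific rule detection, margin dilution of raw centroids — not
clinical-grade performance on any real cohort.

# Evaluation scenarios and problem sizes

The test suite and `scripts/acceptance.R` run these scenarios at fixed
sizes (chosen as the smallest cohorts at which the contrasts are stable):

* **Clean recovery**: 5 classes x 200 samples/class, effect 4x noise,
  purity 1; an 80/20 stratified split; forest pipeline with 15 genes and 20
  rules per model, 1000 trees. Expected: OOB and held-out accuracy near 1,
  ≥95% of stage-1 genes ground-truth informative.
* **Tie behavior**: 5 classes at effect 1 / noise 0.8 (deliberately hard so
  vote fractions collide); fixed k 2 vs 50; forest ties counted over 1000
  predictions.
* **Platform specificity**: two platforms (one array-like: compression 0.5,
  offset SD 0.6), 10 injected pairs; per seed, k-TSP (with pivot genes) and
  forest models trained on the single clean platform versus the mixed
  cohort; flagged-rule fractions compared by sign test over 5 seeds x 2
  families.
* **Margin sweep**: 5 classes, 1600 genes, 300 informative per class with
  decay 0.99 (so genes at rank 125 are still genuinely differential, as in
  real marker rankings); centroid sizes 10-125 per direction. Raw-centroid
  margins decrease monotonically; centered margins vary < 30% relative.
* **Purity robustness**: classes 1-4 high purity at training (Beta(12,2)),
  class 5 an infiltrated category (Beta(4,6)) whose upregulated program is
  shared with the stromal profile; test samples at purity 0.5. The raw
  centroid collapses toward the infiltrated class; rule-based predictors
  degrade gracefully.

# Numerical choices and degenerate inputs

* Exact rule ties (equal expression) are FALSE; exact score ties set the
  tie flag and report the lexicographically first class — deterministic and
  auditable everywhere.
* Ranks use the average-rank tie convention.
* Stratified splitting rounds per-class counts and clips so both sides
  retain every class; classes with fewer than 2 samples are refused for
  training.
* Zero-variance sample vectors make Pearson correlation undefined; the
  centroid predictor raises an error naming the samples.
* Centroid prediction drops genes missing from the input (warning) up to a
  20% tolerance, then refuses; k-TSP and NB refuse on any missing gene (no
  imputation in those families, matching their upstream definitions); the
  forest imputes rules up to 50% missingness.
* CV fold counts are capped at the sample count; folds that lose a class
  entirely are skipped in the accuracy average.
* `duplicates = "median"` in `readExpression` median-merges duplicated
  gene rows (probe-to-gene summarization); the default rejects them.

# Known limitations

* The exhaustive NB rule search is quadratic in genes; the
  `candidateGeneCap` pre-filter changes the candidate set relative to a
  truly exhaustive run on large panels.
* Proximity entries for sample pairs never jointly OOB are NA at small tree
  counts.
* The platform-wise and one-vs-one aggregation rules are this package's
  definitions of variants that the k-TSP literature names but does not
  specify; both are flagged in the config and equivalence-tested against
  the defaults in their degenerate cases.
* Boruta-style pruning inherits the usual caveat that correlated
  informative rules can end tentative rather than confirmed.
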