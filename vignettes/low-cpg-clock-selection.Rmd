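---
title: "Selecting small CpG panels for epigenetic clocks"
author: "cpgSieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting small CpG panels for epigenetic clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgSieve)
```

## The problem

DNA-methylation arrays measure, at each CpG site, the fraction of
methylated signal (a *beta value* in [0, 1]). Epigenetic clocks are
linear models predicting chronological age from these betas; the
classical ones use tens to hundreds of CpGs chosen by a penalized
regression over the full array. For assay design and biological
interpretation, much smaller panels are attractive — but finding them in
a feature space of several hundred thousand CpGs, with only a few
hundred samples, is a wide-data feature-selection problem.

cpgSieve implements a toolkit of selectors aimed at that regime, a
workflow that stabilises their output across cross-validation folds, and
elastic-net clock fitting to score the resulting panels. Every selector
exposes one contract, `selectFeatures(selector, m) -> FeatureSet`, which
makes them freely composable.

## The data container

`MethylationExperiment` extends `SummarizedExperiment`: the `"betas"`
assay holds CpGs (rows) by samples (columns), and `colData()$age` holds
chronological age in years. `betas()` returns the transposed samples ×
CpGs design view that all estimators consume. Validity enforces the
beta range, unique identifiers, and non-negative ages. Matrices without
ages can only be read through `loadPredictionMatrix()` and only feed
`predictAge()` — every selector is supervised and demands labelled data.

Both delimited layouts (samples-in-rows and GEO-series-matrix-style
CpGs-in-rows) are read and written behind an explicit `layout` flag. The
flag is never guessed: a silently transposed methylation matrix is a
classic, hard-to-notice analysis bug. Empty cells and `NA`/`NaN`/`NULL`
tokens are missing markers, because public exports vary. Before
cross-dataset work, `dropIncompleteCpgs()` restricts all matrices to the
CpGs that are present and complete in every one of them.

## The selectors

**Univariate ranking (`selectKBest`).** Scores each CpG by the absolute
Pearson correlation of its betas with age and keeps the top *k*. For a
single predictor this ranking is equivalent to the univariate regression
F statistic, so "correlation value" is implemented as |r| without tying
the package to any particular library default. Zero-variance columns
get score 0 rather than NA. Typical use: *k* = 25 as a standalone panel,
*k* = 2000 as a pre-reduction.

**Variance threshold.** Keeps CpGs whose *population* variance strictly
exceeds *t*. Fast, crude, included for completeness; on methylation
data most of the array varies little, and the method's accuracy reflects
that.

**Model thresholding (`selectFromModel`).** Fits one estimator and keeps
CpGs with importance ≥ *t* (defaults to 0.01; the useful band in
practice is 0.01–0.5, above which selections collapse to empty — an
empty result is returned, not an error). Importance is the absolute
unstandardized coefficient of a fixed-penalty elastic net, or the mean
impurity importance of an extremely-randomized-trees ensemble
(`ranger`, `splitrule = "extratrees"`, whole-sample training, one
random split per candidate — the construction whose randomized splits
make it much faster than a classic random forest at equal tree count).
Coefficients are left unstandardized because betas already share the
[0, 1] scale; a `standardize` flag exists on the clock side.

**Percentage-based RFE (`pctRfeSelect`).** Classic recursive feature
elimination removes a fixed number of features per refit, which is
hopeless when you must travel from 473,035 features to 100. %-RFE
instead removes `max(1, floor(pct * p_current))` features per iteration
(`removalCount()`): 4730 features at p = 473,035, a single feature at
p = 100. `floor` (not `round`) is used so those two printed worked
examples hold exactly. The fraction applies to the *current* feature
count — that is the reading under which the step "scales dynamically"
and reaches the one-at-a-time regime near the end. When a step would
overshoot, only `p_current − targetN` features are removed, so the loop
terminates at exactly `targetN`. Ties at the elimination boundary are
broken lexicographically by CpG id, making results invariant to column
order. The default importance backend is the penalized-linear one
(speed; the tree backend exists for parity), and the iteration count is
bounded by the geometric decay of the survivor count.

**Shadow-feature selection (`borutaSelect`).** All-relevant selection:
each iteration appends to every real CpG a freshly permuted "shadow"
copy (`makeShadowFeatures()`), fits a random-forest regressor on the
doubled matrix, and records a hit for every real CpG whose impurity
importance beats the benchmark. Two open points in the verbal
description were settled as follows, with the alternative kept behind a
flag: the benchmark is the *maximum* shadow importance
(`compare = "max"`, the canonical construction; `"own"` compares each
CpG to its own shadow), and "consistently beats" is formalised as a
one-sided binomial test of the hit count against Binomial(iterations,
0.5) at level alpha with Bonferroni correction across features — the
package does not keep a "tentative" category because the downstream
workflow needs a single set. Shadows are regenerated every iteration;
that is what makes the hit count a repeated trial. De novo on an entire
array the affordable configuration is 7–8 trees for 100 iterations; the
intended use here is after a cheap reduction (KBest to 2000), where the
default 100-tree forest is fine.

**Genetic algorithm (`gaSelect`).** A population of fixed-size feature
subsets ("creatures") evolves under culling, breeding and mutation, with
fitness = held-out R² of an elastic-net clock on the creature's
features. Reference configuration: 3000 creatures × 50 features, 50%
culling, mutation replacing 30% of a child's features. Points the
verbal description leaves open, decided here: the mutation trigger is a
per-child probability of 0.5 (configurable); parents are drawn uniformly
among survivors (fitness-weighted drawing is behind the `polygamy`
flag, and fitness-scaled offspring counts behind `litterScaling`, both
off by default); stopping is a fixed generation count with an optional
fitness threshold. Survivors carry over unmodified each generation —
elitism holds by construction, giving the testable invariant that the
per-generation best fitness (recorded in the result's provenance) never
decreases. The fitness model is a single fixed-penalty elastic net
(alpha 0.5, lambda 0.01) on one seeded split reused for the whole run,
with fitness cached for surviving creatures: tuning penalties inside a
3000-creature population would multiply the cost by two orders of
magnitude for no ranking benefit.

**Neural-network perturbation (`nnPerturbationSelect`).** After a
pre-reduction to ≤ 100 CpGs (the canonical route is %-RFE; compose via
`chainSelectors()`), a small feed-forward regressor is trained once as a
benchmark, then twice per CpG on copies of the data with that CpG's
column forced to 1 and to 0 — both extremes, to cover CpGs whose
natural values sit near either end. The score is
|benchmark − mean(score₁, score₀)|; the top 50–75 (default 65) are
returned. Design choices: the network is a single 32-unit hidden layer
with logistic activations, linear output, BFGS training on range-scaled
ages with weight decay — deliberately the smallest architecture that
ranks planted against null CpGs reliably; the difference is taken in
absolute value; per-feature trainings fit on the training split only;
and all trainings reuse one initialisation seed so deltas measure the
perturbation rather than initialisation noise. Total trainings are
exactly 1 + 2p.

## The workflow

`runCvSelection()` assigns samples to *k* seed-deterministic folds
(default 10) and runs every configured selector on each fold's training
samples only. Per-fold results feed four stabilisation operations, all
pure functions of the records: per-method union of unique features
(`aggregateUnique()`), per-fold all-method intersection refined by a
shadow-selection pass (`intersectPerFoldThenRefine()`), the all-method
intersection of aggregated sets (`postSelectionIntersection()`, where an
empty result is legitimate), and frequency ranking
(`topFrequent()`, counting one appearance per (method, fold) record,
with per-method counting behind a flag; ties break lexicographically).
A selector failing on one fold is logged and excluded rather than
aborting the run.

Every resulting panel is scored by `evaluateFeatureSet()`: by default 10
repeated seeded 80/20 train/test splits, fitting a fresh internally
tuned elastic-net clock per split and reporting mean R², its SD, and
mean/median absolute error in years. The protocol is described in the
field both as "10-fold CV" and as "80/20 done 10 times"; the literal
80/20 × 10 reading is the default and a strict 10-fold (90/10) partition
is available as `mode = "kfold"`. No claim is made about which protocol
any particular published number used.

## The clock

`fitClock()` minimises the unscaled elastic-net objective
Σ(yₐ − b − Σβx)² + λ₁Σ|β| + λ₂Σβ². Fitting is delegated to coordinate
descent (glmnet) through the exact mapping λ₁ = 2nλα,
λ₂ = nλ(1 − α) between this objective and glmnet's per-observation
parameterisation; the λ₁ = 0 case (ridge/OLS) is solved in closed form
on centred data so the unpenalised fit matches least squares to
numerical precision. When no penalties are given, (λ₁, λ₂) are tuned by
seed-pinned 5-fold internal cross-validation over glmnet's lambda path
crossed with L1-shares {0.1, 0.5, 0.9}; tuning is per fit rather than
shared across an experiment. Features are not standardized by default.
R² is always 1 − SS_res/SS_tot on the evaluation set, reported as NA
when the reference ages are constant (the degenerate-variance case;
absolute errors are still reported). `externalValidate()` predicts on an
independent matrix with no refitting; `transferFit()` instead re-fits
fresh clocks on the new dataset restricted to a transferred panel.
Clocks serialise to human-diffable TSV at full precision
(`saveClock()`/`loadClock()`, bit-exact round-trip).

## The synthetic bench

`generateClockDataset()` emulates the statistical skeleton of a blood
methylation cohort: ages uniform on a range, a small planted set of CpGs
whose mean methylation is clamped-linear in age, Gaussian observation
noise, and age-independent null CpGs. The clamped-linear link (rather
than a logistic one) keeps planted effect sizes transparent, so recovery
tests have an unambiguous ground truth; the clamp preserves the beta
range.

The documented bench conditions are n = 200 samples, p = 1000 CpGs,
k = 5 informative CpGs with slopes ±0.004 beta/year, noise SD 0.03 and
ages 20–90 years. The slope mimics the strongest known single-CpG age
signals (the ELOVL2 class, whose methylation moves by roughly 0.2–0.3
beta units across the adult lifespan), and the size keeps every selector
in the seconds-to-minutes range. Structural randomness (which CpGs are
informative, baseline methylation levels) depends only on the spec seed;
sampling randomness additionally depends on a `draw` index, so
`draw = 0, 1, ...` give independent cohorts from the same population —
which is exactly what external-validation and transfer experiments need.

What the generator does *not* emulate: probe chemistry and its
beta-value compression, cell-composition and batch structure, nonlinear
age trajectories, and correlation between CpGs. Passing recovery tests
on this bench therefore demonstrates that the algorithms find planted
monotone age signal against independent noise at realistic effect
sizes — not that they are robust to confounding in real cohorts.

## Numerical choices and degenerate inputs

* Ranking ties everywhere: larger score first, then lexicographic CpG
  id. This makes every selector deterministic and column-order
  invariant.
* Zero-variance CpGs: correlation defined as 0 (KBest); removed at any
  threshold ≥ 0 by the variance filter.
* Seeds: every stochastic entry point takes an integer seed, pins its
  private RNG stream, and restores the caller's `.Random.seed`. Derived
  seeds (per iteration, per split) stay within 32-bit range.
* Empty results: a thresholded selection may legitimately be empty and
  is returned as such; an empty *stage* inside a chain is an error
  (continuing would select from nothing); the all-method intersection
  may be empty by design.
* Problem sizes in the test suite: recovery properties run at the bench
  conditions above (10 seeds where a success fraction is asserted);
  oracle-equivalence checks run on 30-feature toys where exhaustive
  step-1 RFE is cheap; decorrelation of null CpGs is checked at
  n = 2000.

## Known limitations

The selectors assume a complete matrix — imputation is out of scope, and
`dropIncompleteCpgs()` is deliberately conservative. Age-transformation
link functions (log-linear warping of young ages) used by some published
clocks are not implemented. The genetic algorithm's defaults are tuned
for array-scale inputs; at bench scale a smaller population converges
faster. The neural-network selector trains 2p + 1 networks and is only
sensible after aggressive pre-reduction.

## A minimal run

```{r example, eval = FALSE}
ds <- generateClockDataset(syntheticSpec(seed = 7))
methods <- list(
    kbest25 = kBestSelector(25),
    kbest_boruta = chainSelectors(kbest = kBestSelector(200),
                                  boruta = borutaSelector(seed = 7)))
res <- runWorkflow(ds$matrix, methods, folds = 10, seed = 7)
reportMetrics(res$reports$kbest_boruta)
annotateFeatures(res$panels$top5_frequent, c(cg16867657 = "ELOVL2"))
```
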