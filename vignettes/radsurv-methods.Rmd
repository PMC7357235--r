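---
title: "Predicting glioma survival from clinical and DVH features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting glioma survival from clinical and DVH features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsurv)
```

# Overview

`radsurv` implements a survival-time prediction pipeline for patients
with malignant glioma treated with radiotherapy, together with a
per-patient what-if simulation of treatment strategy. The pipeline has
five stages:

1. **Feature construction.** From each patient's cumulative dose-volume
   histograms (DVH) of four target structures (PTV/CTV, local and
   extended) the package computes D~X~ (the minimum dose received by the
   hottest X% or X cm^3 of the structure), V~X~ (the volume receiving at
   least X Gy), max/min/mean dose, and treatment-level scalars
   (prescription dose, treatment duration, gamma-knife boost flag,
   target volume, biologically effective dose). Together with eight
   clinical features this yields the candidate inventory of
   `feature_inventory()`.
2. **Regression model.** Survival time in days is predicted by
   epsilon-insensitive support vector regression (SVR) with a radial
   basis function kernel.
3. **Feature and hyperparameter selection.** A genetic algorithm (GA)
   searches simultaneously over the SVR hyperparameters (C, epsilon,
   gamma) and the binary feature mask. The fitness of a chromosome is
   the Akaike information criterion computed from leave-one-out
   cross-validation (LOOCV) residuals.
4. **Evaluation.** Clinical-only, DVH-only and combined models are
   compared by mean LOOCV residual error, paired Wilcoxon signed-rank
   tests, Kaplan-Meier curves of actual versus predicted survival with a
   log-rank test, and a median-split classification AUC.
5. **What-if simulation.** For an individual patient, prescription dose
   and treatment duration are swept through the trained combined model,
   with the selected DVH features recomputed from dose-rescaled curves.

Because clinical DVH datasets of this kind are private, the package
ships a seeded synthetic-cohort generator with a known sparse
ground-truth survival model; every stage of the pipeline is tested
against that generator.

# The regression model

## epsilon-SVR and its parameters

For features $x$ and survival $y$ (days), the model is
$f(x) = \sum_i \beta_i K(x_i, x) + b$ with the RBF kernel
$K(u, v) = \exp(-\gamma \lVert u - v \rVert^2)$. Training solves the
standard dual problem of the epsilon-insensitive loss: residuals smaller
than $\varepsilon$ (days) are free, larger ones are penalized at rate
$C$. The three tunables are:

* `C` (> 0, unitless): regularization/penalty weight. Decoded range
  $[2^{-5}, 2^{15}]$.
* `epsilon` (days, >= 0): insensitive-zone half width. Decoded range
  $[10^{-2}, 10^{2}]$.
* `gamma` (> 0, per squared standardized feature unit): kernel
  amplitude. Decoded range $[2^{-15}, 2^{3}]$.

The solver is an in-package sequential minimal optimization (SMO)
routine on the 2n-variable dual with maximal-violating-pair working-set
selection, written in C++ for the throughput the GA wrapper needs
(about $10^5$–$10^6$ small fits per selection run). The stopping
tolerance scales with the target magnitude,
`1e-5 * (1 + max(abs(y)))`, so fits are equally tight on day-scale and
unit-scale targets. The bias is the mean Karush-Kuhn-Tucker estimate
over free support vectors; when no support vector is free the dual only
determines an interval, and the midpoint is used — this convention is
part of the model definition and the test oracles reproduce it.

## Preprocessing

Feature scaling and categorical encoding are part of the model
contract: categorical features are one-hot encoded (binary features as
a single 0/1 indicator), numeric columns are z-scored with the mean and
*population* standard deviation of the training rows, and constant
columns are mapped to zero with a unit scale. Category levels are part
of the declared data schema (not statistics), so encodings are
identical across cross-validation folds, while standardization
statistics are re-estimated inside every fold to avoid leakage. Gamma
is defined on standardized features, which keeps the decoded gamma
range scale-free.

# Feature selection by genetic algorithm

## Chromosome and decoding

A chromosome is a bitstring with three 12-bit parameter segments
followed by one mask bit per candidate feature. A segment read as an
unsigned integer $v$ of $b$ bits decodes log-uniformly:
$\mathrm{param} = lo \cdot (hi/lo)^{v/(2^b - 1)}$. An all-zero mask is
repaired by activating one random bit, so every evaluated individual
selects at least one feature.

## Fitness

The fitness (smaller is better) is
$$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(k + 1),$$
where RSS is the sum of squared LOOCV residuals, $n$ the number of
patients and $k$ the number of selected features (the $+1$ counts the
residual variance). This Gaussian-residual form penalizes complexity,
so parsimonious models are favoured. RSS is clamped below at $10^{-12}$
so a perfect fit stays finite, and a solver failure on any fold is
recorded as an infinite fitness rather than an error, keeping the
search total. Counting support vectors instead of features as $k$ was
rejected: support-vector counts are solver- and tolerance-dependent,
which would make the fitness irreproducible.

Inside the fitness, the LOOCV folds are warm-started from the full-data
dual solution (with the held-out point's coefficients removed and the
equality constraint repaired); each fold is still solved to the same
KKT tolerance, so warm and cold paths agree to solver precision
(~0.3 days on a 500-day scale, far below selection resolution).
`loocv_predict()` defaults to cold, independent per-fold fits.

## Genetic operators

Standard choices, all configurable: tournament selection of size 2,
uniform crossover with rate 0.8, bit-flip mutation with a
per-individual budget of 0.3 expected flips spread uniformly over the
bits, and 1-elitism (the best individual survives unchanged, making the
best-so-far fitness non-increasing). The study-faithful budget is a
population of 500 evolved for 1000 generations; a reduced `"ci"`
profile (30 x 40) covers smoke runs. Mask bits initialize sparsely
(probability 0.15) to match the parsimony pressure of the AIC fitness.

# Evaluation methodology

* **Residual error** is `|actual - predicted|` per patient from LOOCV;
  models are summarized as mean ± sample (n-1) standard deviation.
* **Wilcoxon signed-rank** (paired) compares residual vectors. Zero
  differences are dropped (flagged), tied absolute differences receive
  mid-ranks, and for up to 25 nonzero pairs the p-value is exact,
  computed from the full distribution of the rank sum (equivalent to
  enumerating all $2^m$ sign patterns); beyond that a normal
  approximation with tie and continuity corrections is used.
* **Kaplan-Meier / log-rank**: the actual survival times and the
  combined model's predictions are compared as two fully-observed
  samples by the product-limit estimator and the standard
  observed-minus-expected log-rank chi-square (1 df), via the survival
  package. Treating model predictions as an independent sample is
  statistically unusual but is exactly the comparison the pipeline is
  designed to report.
* **Median-split AUC**: actual survival is binarized at its median
  (values at the median to the lower class) and predictions scored by
  the rank (Mann-Whitney) AUC with ties counted 1/2.

Per-group model selection runs the GA three times, restricting the mask
to the clinical columns, the DVH columns, and their union.

# The synthetic cohort generator

## What it emulates

The generator draws cohorts matching the marginal characteristics of a
published 35-patient malignant-glioma series: ages 11–92 (median ~64),
a 12:23 female:male split, histology dominated by glioblastoma,
19:16 normal:abnormal mental status, symptom durations 27–3119 days,
prescription doses 30–80 Gy concentrated at 60 Gy, treatment durations
19–80 days (median ~50), and survival times with median near 504 days.
All patients are uncensored (followed until death).

DVH curves are smooth logistic sigmoids in dose, centred near the
prescription and truncated to reach zero at 1.12 x prescription, with
an optional cold-spot mixture: a patient-specific fraction of the
volume whose coverage falls off around 75% of the prescription. The
dose grid is refined around the sigmoid centres so sharp fall-offs
(up to the uniform-irradiation step limit at infinite homogeneity) are
represented faithfully by the piecewise-linear curve.

## Ground truth

Noise-free survival is
$$y = \mathrm{intercept} + \textstyle\sum_j c_j z_j +
  \mathrm{doseresp}(d; p_i) - 2(\mathrm{duration} - 50) + \mathrm{noise},$$
floored at 1 day. The default truth is sparse (five nonzero
coefficients: age -80, abnormal mental status -120, symptom duration
+50, target volume -90, PTV~local~ D98 +70 days per standardized unit)
and deliberately mixes clinical with DVH signal loading on two distinct
mechanisms — tumor burden (target volume) and coverage (D98, which
reflects cold spots). Reference centers and scales are the generator's
own marginal moments, so "days per standardized unit" is literal. The
dose response rises at 5 days/Gy above 30 Gy to a per-patient plateau
$p_i$ and declines at 8 days/Gy beyond it (toxicity of escalation past
tolerance). The plateau is driven by the patient's cold-spot fraction
— underdosed tumors benefit from escalation up to a higher dose — so
the per-patient optimum is *observable* in the DVH features and a
model can, in principle, recover it.

Two design points deserve emphasis:

* **The what-if ground truth includes feature coupling.** When
  prescription dose is swept, dose-linked DVH features in the truth
  (D98) rescale with it and add roughly +5 days/Gy on top of the
  explicit dose response. `true_whatif_survival()` therefore computes
  the generator's answer to a dose change by rescaling the curves and
  re-extracting features, exactly as the simulation does for the
  model. The default post-plateau decline (8 days/Gy) is chosen so the
  *total* response retains an interior per-patient optimum; with a
  shallower decline the optimum degenerates to the sweep boundary for
  every patient and per-patient optimization is vacuous.
* **Recovery benchmarks need an identifiability cap.** The DVH
  inventory contains near-duplicates by construction (V~5cc~–V~15cc~
  equal the structure volume; most absolute-Gy features co-scale with
  the prescription). A proxy subset can match the truth's fit, in
  which case "recovery of the named features" is undefined — we
  verified that a proxy mask attains a *lower* AIC than the truth mask
  on such cohorts. `make_recovery_dataset()` therefore samples
  distractors whose absolute correlation with every informative
  feature stays below 0.6 (relaxed in 0.05 steps if a particular
  cohort leaves too small a pool).

## What it does not emulate

Inter-feature correlation of real cohorts is unknown; the generator's
correlations arise mechanically from the DVH construction. Censoring,
toxicity outcomes, imaging/radiomics features and plan re-optimization
under dose changes are out of scope. Passing recovery and comparison
tests on this generator demonstrates that the pipeline's machinery is
correct and that its statistics behave as designed — not that the
clinical effect sizes are realistic.

# What-if simulation

`simulate_dose_change()` follows a three-step procedure: set the
prescription-dose feature to the new value; rescale the four DVH curves
multiplicatively (dose axis times `new/old`, volumes unchanged — the
simplest model consistent with re-planning at a different prescription)
and recompute exactly the model's selected DVH features, including BED
at the new dose with unchanged fractionation; then predict. Only
selected features are recomputed; unselected features are untouched
even if dose-dependent. At the actual dose the transform is the
identity, bit for bit. `dose_duration_surface()` additionally overrides
the treatment-duration feature per grid cell; a duration change updates
only that feature (the default BED carries no time term, since duration
is its own candidate feature). Sweep bounds default to the cohort's
observed ranges (30–80 Gy, 19–80 days) to avoid evaluating the RBF
model far outside its support.

# Numerical choices and edge cases

* DVH interpolation is linear on the cumulative curve; D~X~ returns the
  smallest qualifying dose on flat segments; `min` dose is the dose
  covering 100% of the volume, `max` the dose where the curve reaches
  zero; the mean integrates the piecewise-linear curve exactly
  (trapezoid), with a point mass at the last dose if a curve is
  truncated above zero.
* For the cm^3 referent of D~X~, thresholds exceeding the structure
  volume are clamped to the total volume.
* BED uses the linear-quadratic form $D(1 + d/(\alpha/\beta))$ with
  $\alpha/\beta$ = 10 Gy by default and no time factor; whether a
  repopulation correction should apply is left to the caller via the
  `alpha_beta` argument and the duration feature.
* Both D~X~ referents (percent and cm^3) are computed and named
  distinctly (e.g. `PTVlocal_D50pct`, `PTVlocal_D50cc`); the package
  fixes its own documented inventory of 8 clinical + 241 DVH candidate
  features rather than reproducing any particular historical count,
  since published feature tables of this kind underdetermine the exact
  inventory.
* Degenerate cases are defined, not accidental: constant columns map to
  zero; empty masks are repaired; all-zero Wilcoxon differences return
  a flagged p of 1; a single residual reports sd 0 with a degenerate
  flag; a log-rank comparison where one group has no events raises an
  error naming the problem.
* Seeds: every generator and GA entry point takes an explicit seed; the
  pipeline derives per-stage seeds from one global seed by fixed
  offsets, so stages are individually reproducible.

# Problem sizes used by the test-suite experiments

The packaged experiments run at desk scale, chosen so each stage's
statistical claim is testable with comfortable margins: recovery
benchmarks use cohorts of n = 60 with 50 candidate features and a GA
budget of 60 x 60 (five seeds); the three-group comparison uses n = 80
with a 24 x 25 GA budget per group (five seeds); what-if argmax
recovery uses a noise-free cohort of n = 60 on a 5-Gy dose grid. The
study-faithful GA budget (500 x 1000) remains the package default for
real analyses.

# Known limitations

* The GA fitness is a noisy, expensive black box; the reduced budgets
  used in tests trade search depth for runtime and can miss weak
  signals (the +50 days/sd symptom-duration effect sits near the
  detection limit at n = 60 with 100-day noise).
* The log-rank comparison of actual versus predicted survival treats
  predictions as an independent sample; its p-value should be read as
  a descriptive calibration summary, not an inference.
* The dose-rescaling model ignores plan re-optimization; real DVHs
  under a different prescription would not scale exactly
  multiplicatively.
* Recovery of the per-patient optimal dose depends on how sharply the
  fitted model resolves the post-plateau decline, which in turn
  depends on the cohort draw (how many patients were prescribed above
  60 Gy); across generator seeds the argmax agreement at n = 200
  ranges from roughly 60% to 90%.
* Figure-style captions in published work sometimes attribute the
  group comparison to a paired t-test; the package implements the
  Wilcoxon signed-rank test throughout, which is what the accompanying
  analysis text specifies.
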