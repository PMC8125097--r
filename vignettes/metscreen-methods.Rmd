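---
title: "Methods: age-standardized adiposity indexes as MetS screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-standardized adiposity indexes as MetS screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscreen)
```

## The problem

Metabolic syndrome (MetS) — the clustering of central obesity, raised
blood pressure, raised triglycerides, low HDL-cholesterol and raised
fasting glucose — is common in women with obesity and becomes more common
with age. Clinicians want a cheap anthropometric index whose value flags
the women most likely to have MetS, and a threshold for that index that is
appropriate for the patient's age. `metscreen` implements the whole
evaluation chain for six candidate indexes (BMI, FMI, FFMI, TMI, WtHR,
BMFI): rule-based MetS labelling, age-standardization of each index,
ROC-based comparison of the candidates, and the translation of the chosen
operating point back into age-specific raw-scale thresholds.

## MetS labelling

The rule engine applies the component definitions with their printed
inclusivity and nothing else: waist circumference ≥ 80 cm; SBP ≥ 130
and/or DBP ≥ 85 mmHg or antihypertensive treatment; TG ≥ 150 mg/dL or
lipid-lowering treatment; HDL-C < 50 mg/dL (a value of exactly 50 is not
low, and no medication rescues or triggers this component); glucose ≥ 100
mg/dL or antidiabetic treatment. MetS is any three of the five. The strict
IDF variant in which central obesity is mandatory is available as
`classify_mets(..., require_central_obesity = TRUE)` but is off by
default, since the three-of-five rule is the one the pipeline evaluates.
Lipid-lowering treatment counts toward the triglyceride component only:
that is the literal placement of the treatment clause, and moving it to
HDL would change prevalences silently.

## Age-standardization by median regression

Reference-curve methods (LMS and relatives) model how an anthropometric
quantity's distribution shifts with age. Here the median curve of each
index is fitted on the log scale by quantile regression at τ = 0.5 with
the design {1, a³, a⁴}, a = age/100:

ln v ≈ β₀ + β₃a³ + β₄a⁴.

Choices worth making explicit:

* **Basis.** Cubic-plus-quartic terms around an intercept, no linear or
  quadratic terms. This is deliberately the minimal form; the full quartic
  {1, a, a², a³, a⁴} is available via `basis = "full_quartic"` for
  sensitivity analyses. Over ages 18–83 the two extra monomials change
  fitted medians only slightly but cost identifiability (see below).
* **Age rescaling.** a = age/100 keeps the design matrix conditioned: raw
  age⁴ reaches ~4.7·10⁷ at age 83 and would swamp the intercept column.
* **Residual scale.** "Standardized residuals" is read in its simplest
  sense: residuals of the τ = 0.5 fit divided by their global sample SD,
  so the cohort's standardized values have SD 1 by construction. A robust
  quantile-spread estimator (q₀.₇₅ − q₀.₂₅)/1.349 is available via
  `scale_estimator = "iqr"` for heavy-tailed indexes.
* **Solver.** The pinball loss Σρ_τ(u) is minimized by iteratively
  reweighted least squares on an ε-smoothed loss (final ε = 1e-6, tol
  1e-8, ≤ 200 iterations per smoothing stage), with a continuation
  schedule ε: 1e-2 → 1e-6 so the iterate is not trapped by a poor initial
  active set, and a final active-set polish that snaps to the exact
  interpolating solution through the p smallest-residual points whenever
  that lowers the loss (a median-regression optimum interpolates p
  points). The test suite validates the solver against a combinatorial
  oracle that enumerates all interpolating subsets on small instances.
  Non-convergence is recorded in `fit_diagnostics` and the best iterate is
  returned rather than erroring, since a usable curve with a diagnostic
  beats an aborted analysis.
* **Degenerate input.** Constant (zero-spread) index values make the
  residual scale collapse; standardization is then undefined and the fit
  is rejected with an explicit error rather than returning z-scores that
  would be ±∞.

The age-adjusted score is z = (ln v − median̂(age))/s. For fixed age this
is strictly increasing in v, so ROC analysis on z within an age stratum is
identical to ROC analysis on the raw index; across ages it removes the
shared age trend so one cutoff z* serves all ages. The raw-scale
threshold curve is cutoff(age) = exp(median̂(age) + z*·s).

**Identifiability caveat.** Over ages 18–83, a³ and a⁴ correlate at
≈ 0.998, so (β₃, β₄) are individually poorly identified: at n = 5000 and
log-scale noise σ = 0.1 their sampling SDs are ≈ 0.10–0.18 (measured by
simulation), even though the fitted median *curve* — the only thing
standardization uses — is recovered to < 0.005 log units across the age
range. Users should treat the curve, not the coefficients, as the
estimand; the test suite checks both, at the tolerances each can support.

## ROC machinery

The ROC implementation fixes conventions that standard libraries vary on:
thresholds are the observed score values, a subject is test-positive iff
score ≥ threshold, all indexes share the higher-score-is-riskier
orientation (including FFMI), and Youden ties break toward the smallest
cutoff (the more sensitive operating point, appropriate for screening).
AUC is the trapezoidal area, identically the tie-corrected Mann–Whitney
statistic; its variance and the paired comparison of two indexes measured
on the same subjects use the DeLong structural components, with normal
CIs. Pairwise p-values are reported unadjusted (a Bonferroni option exists
in `anova_bonferroni` for group contrasts, but the AUC comparison matrix
is reported raw). The suite cross-checks AUC, variance and the paired test
against pROC, and the variance against a jackknife, neither of which is
used in the implementation.

Predictive values and likelihood ratios are pure functions of
(sensitivity, specificity, prevalence) through the Bayes identities, and
every assembled report is audited against those identities before it is
returned. The flagged fraction (share of the cohort testing positive) is
reported twice: once from the identity se·π + (1−sp)(1−π) and once counted
empirically from the data. At printed rounding the two can disagree — in
the reference diagnostic table two cells (WtHR 55.7%, FMI 15.2%) do not
close under the identity (they compute to 53.6% and 15.4%, and FMI's PPV
prints 71.5% where the identity gives 71.4%), presumably because flags
were counted on raw data; the package therefore always reports both
values rather than targeting either.

## The synthetic cohort

The generator emulates the statistical structure the analysis depends on,
not the full joint distribution of a real cohort:

* ages truncated-normal 50.8 ± 14 on [18, 83]; heights normal 161.5 ± 6 cm
  (a typical value for the population, not an observed cohort moment);
* BMI = 30 + lognormal(2.5023, 0.4225), giving mean ≈ 43.3 and SD ≈ 5.9
  above the BMI ≥ 30 inclusion floor; weight back-solved from BMI and
  height;
* waist = 50.6 + 1.6·BMI + 0.3·(height − 160) + N(0, 6), floored at
  80.1 cm so every subject is centrally obese (as in the target
  population); the affine form is an acknowledged approximation — the
  real WC–BMI–height covariance is not published;
* FM% normal 50.8 ± 5.35 clipped to (25, 70); FFM% = 100 − FM%;
* each of the four non-anthropometric components follows a logistic model
  on the standardized log-WtHR (slope 0.70) and standardized age (slope
  1.30), with intercepts calibrated by bisection on the generated
  covariates so realized prevalences match the targets 72.3%, 33.4%,
  54.0%, 33.0%; the slope pair was calibrated once so that the
  age-standardized WtHR discriminates MetS with AUC ≈ 0.66 and the MetS
  prevalence lands at ≈ 60%, the regime the pipeline is meant to operate
  in;
* medication flags are drawn among component-positive subjects at rates
  giving marginal prevalences 54.5% (BP), 7.9% (lipid), 16.7% (glucose),
  so a flag always implies its component;
* continuous risk values are drawn from truncated normals (lognormal for
  TG) on the side of the clinical cutoff consistent with the component
  indicator — untreated component-positives qualify on values, treated
  ones may be controlled — so the rule engine reproduces the generator's
  labels exactly.

What this generator does **not** emulate: the published cohort's exact
means and covariances (unavailable as a joint distribution), menopause
biology, BMI-class substructure, or measurement error in anthropometry.
Passing tests therefore demonstrate that the pipeline recovers the
structure it assumes — calibrated prevalences, a known index–MetS
association, age-dependent thresholds — not that it reproduces any
particular cohort's numbers, which would require the original data.

## Problem sizes and numerical settings

The test suite and drivers use cohorts of 1528 (the study scale), 5000
(recovery checks) and 20000 (prevalence calibration); the DeLong null
calibration uses 2000 replicates of n = 300; the oracle equivalences run
on ~100 small random instances. These sizes put Monte-Carlo error
comfortably inside the asserted bands (e.g. binomial SD ≈ 0.0033 on a
prevalence at n = 20000 against a ±0.01 band). Quantile-fit tolerances:
smoothing ε = 1e-6, coefficient tol 1e-8; round-trip standardization is
exact to 1e-9 relative; AUC equals the Mann–Whitney form to 1e-12.

## Limitations

* The quantile-regression basis is fixed to the quartic family; no
  non-crossing multi-quantile fitting or full LMS (Box–Cox) machinery.
* DeLong CIs use the normal approximation; no bootstrap.
* The correlated-correlation test is the overlapping-variables
  (Meng–Rosenthal–Rubin) form; other dependent-correlation designs are
  out of scope.
* The impedance index ZI₅₀ is computed but no impedance-to-composition
  prediction equations are included: FM% and FFM% are inputs.
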