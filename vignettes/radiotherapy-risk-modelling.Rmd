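---
title: "Modelling radiation pneumonitis and secondary cancer risk in matched breast-cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radiation pneumonitis and secondary cancer risk in matched breast-cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtrisk)
```

## The problem

Breast-cancer radiotherapy delivered with intensity-modulated (IMRT) or
volumetric-modulated arc (VMAT) techniques trades off two kinds of lung and
organ-at-risk exposure.  Acutely, dose to the ipsilateral lung drives
radiation-induced pneumonitis (RP); chronically, the dose bath over
surrounding organs carries a secondary-cancer induction risk (SCR).
Comparing the two techniques on observational cohorts requires three
ingredients that this package implements end to end:

1. **confounder control** — propensity-score matching of the treatment
   arms on baseline covariates;
2. **an acute-toxicity dose-response** — selection of the dominant
   dosimetric predictor by cross-validated LASSO, followed by a
   Lyman-Kutcher-Burman (LKB) normal tissue complication probability
   (NTCP) model fit by maximum likelihood;
3. **a chronic-risk model** — Schneider's full mechanistic
   carcinoma-induction models (risk-equivalent dose, organ equivalent
   dose, excess absolute risk) evaluated per organ at risk.

Everything operates on dose-volume histograms (DVHs) plus a small set of
per-patient covariates, so the pipeline is treatment-planning-system
neutral.  Because real patient records of this kind are access-restricted,
the package also ships a synthetic cohort generator with known ground
truth; it is first-class, tested code and the substrate for most of the
test suite.

## Dose-volume histograms and dosimetric factors

A `dvh` stores one organ's curve in cumulative form (percent volume
receiving at least each dose, anchored at `V(0) = 100`) or differential
form (percent volume per dose bin, summing to 100).  Conversions between
the two are exact inverses; `v_at()` interpolates the cumulative curve
linearly, matching the "volume receiving at least x Gy" reading of the
V~x~ metrics.  The candidate-predictor set for the pneumonitis analysis is
the mean lung dose MD plus V~5~, V~10~, ..., V~50~ of the ipsilateral lung
(the IV~x~ metrics).  The threshold list is configurable rather than
hard-coded: under a 5-Gy step the conventional "MD + IV5-IV50" panel
contains 11 candidates, and nothing in the method depends on the exact
count.

Volumes are relative throughout; absolute organ volume is carried only as
metadata because every downstream quantity (V~x~, MD, OED weights) uses
volume fractions.

## Propensity matching

The propensity model is a maximum-likelihood logistic regression of
`P(VMAT)` on age (continuous), AJCC stage (ordinal 1-3), supraclavicular
irradiation and chemotherapy (binary).  Matching is greedy 1:1
nearest-neighbour on the absolute difference of logit propensities,
without replacement, with a caliper of 0.2 times the standard deviation of
the logit scores pooled over both arms; treated units are processed in
descending propensity order and distance ties resolve to the smaller
control id, which makes the result invariant to input row order.  Greedy
caliper matching is the conventional reading of the SPSS-style recipe; the
caliper SD is computed on the pooled cohort because the standard
recommendation does not restrict it to one arm, and distances are measured
on the logit scale, on which the caliper is defined.  Optimal
(network-flow) and many-to-one matching are out of scope.

`balance_diagnostics()` reports standardized mean differences and
two-sided test p-values (rank-sum for age, chi-square for categorical
covariates) before and after matching; on confounded synthetic cohorts the
mean absolute SMD decreases after matching, which the test suite asserts.

## LASSO selection of the dominant factor

The selector minimises the L1-penalized binomial objective
`-(1/n) loglik + lambda * sum(|beta|)` over a decreasing grid of 100
log-spaced lambdas from the closed-form `lambda_max` down to
`1e-3 * lambda_max`, on internally standardized predictors.  Each
per-lambda weighted least-squares subproblem is solved by coordinate
descent sweeps that grow and shrink the active set, combined with an exact
linear solve on the active block; a solution is accepted only when its
Karush-Kuhn-Tucker conditions hold.  The exact solve matters numerically:
neighbouring V~x~ columns are correlated at 0.9 or above, where plain
cyclic coordinate descent is condition-limited and impracticably slow.
The full-path KKT violation is checked in the tests at 1e-6 and is in
practice at machine precision.

Selection uses stratified 10-fold cross-validation with the
one-standard-error rule: the chosen lambda is the largest whose mean
validation loss is within one SE of the minimum.  The validation loss is
the binomial deviance by default; `loss = "mse"` reproduces the
squared-error reporting convention of some LASSO-GLM implementations, and
the rule itself ("minimum plus 1 SE") is identical under either.  The
dominant factor is the earliest-entering factor active at the chosen
lambda, with ties broken by the larger absolute standardized coefficient;
if the 1-SE model is empty the first factor to enter the path is
reported.  Fold construction is seeded, and folds that would leave a
training set single-class are redrawn with a warning.

## The LKB NTCP model

With the volume parameter fixed at `n = 1` the LKB model needs no
generalized-EUD reduction and reads

$$\mathrm{NTCP}(x) = \Phi\!\left(\frac{x - TV_{50}}{m \cdot TV_{50}}\right),$$

where `x` is the selected dosimetric factor (so `TV50` carries the
factor's units — here percent lung volume), `TV50` is the factor value
giving 50% complication probability and `m` is the dimensionless slope.
`fit_lkb()` maximizes the Bernoulli log-likelihood over
`TV50 in (0, 10 max(x)]`, `m in [0.01, 10]` with bounded quasi-Newton
iterations from 7 deterministic starts (TV50 at sample quantiles crossed
with several slopes) plus 5 seeded jittered restarts; probabilities are
clamped to `[1e-12, 1 - 1e-12]` inside the log-likelihood.  On small
instances the test suite checks that the optimum dominates a dense
200 x 200 parameter grid.

Confidence intervals are profile-likelihood intervals
(`2 dlnL = 3.84` at 95%), chosen over Wald intervals because the slope's
sampling distribution is markedly asymmetric at realistic event counts;
the achieved likelihood-ratio value at each interval endpoint is stored
and asserted to be within 1e-3 of the cutoff (endpoints that run into the
parameter bounds are reported at the bound).

Model performance is summarized by `model_performance()`: AUC
(Mann-Whitney with half-credit ties), the Hosmer-Lemeshow test (10
quantile groups, ties kept together, df = groups − 2), the scaled Brier
score `1 - BS/BS_ref`, and the logistic calibration slope and intercept.
Two conventions deserve a note.  First, df = groups − 2 is the
within-sample convention; when predictions are externally specified true
probabilities the statistic is approximately chi-square with `groups`
degrees of freedom, and the null-distribution test in the suite uses that
reference.  Second, published single-number "Hosmer-Lemeshow" values are
ambiguous between the statistic and its p-value, so the report exposes
both and privileges neither.

Planning thresholds follow by inversion:
`invert_lkb(p) = TV50 (1 + m qnorm(p))`.

```{r}
invert_lkb(0.5, tv50 = 15.07, m = 0.62)    # factor value at 50% risk
invert_lkb(0.25, tv50 = 15.07, m = 0.62)   # ~8.8% at 25% risk
```

## Schneider secondary-cancer risk models

The risk-equivalent dose of the full carcinoma model, with
fractionation-corrected cell-kill parameter
`alpha' = alpha (1 + d / (alpha/beta))` (`d` = dose per fraction,
`alpha/beta` = 3 Gy),

$$\mathrm{RED}(D) = \frac{e^{-\alpha' D}}{\alpha' R}\left[1 - 2R +
  R^2 e^{\alpha' D} - (1-R)^2 e^{-\frac{\alpha' R}{1-R} D}\right],$$

interpolates between the bell-shaped pure cell-kill response (`R -> 0`)
and the plateau response (`R -> 1`); closed-form limit branches take over
within 1e-7 of the `R` boundaries, where the general expression loses
precision to cancellation, and continuity across the switch is asserted at
1e-5.  The printed fractionation rule `alpha' = alpha + beta D` is read
with `beta` the cell-killing beta (`alpha/3` under the stated ratio) and
`D` the dose per fraction at the DVH bin, the standard correction in this
model family; the per-fraction rule is configurable through
`n_fractions`, whose default of 30 matches the 63 Gy / 2.1 Gy-per-fraction
(equivalently 51 Gy / 1.7) simultaneous-integrated-boost prescription.

The organ equivalent dose averages RED over the differential DVH with
bin-volume weights, and the excess absolute risk applies the age modifiers

$$\mathrm{EAR} = \beta \cdot \mathrm{OED} \cdot
  \exp\!\big(\gamma_e (\mathrm{age}_x - 30) +
  \gamma_a \ln(\mathrm{age}_a / 70)\big),$$

in excess cases per 10,000 person-years, with `beta` defined at the
reference ages (exposure 30, attained 70).  `cohort_scr()` excludes
patients older than 65 at treatment, projects to attained age 70, and
compares arms per organ by a two-sided rank-sum test (t-test via config) —
the test behind published per-organ comparisons is typically unnamed, and
rank-sum is the conservative default for skewed dose metrics.  Because an
"accumulated EAR at age 70" admits two readings, both are provided:
`ear()` is the point value at attained age 70 and `accumulated_ear()` sums
yearly EARs from exposure (plus an optional latency, default 0) to 70.

Organ parameters (`alpha`, `R`, `beta`, `gamma_e`, `gamma_a`,
`alpha/beta`) are deliberately *inputs*, loaded from a CSV/YAML config
keyed by organ.  The packaged
`extdata/organ_params_synthetic.csv` is a synthetic template with
field-plausible magnitudes for the six organs at risk (ipsilateral and
contralateral lung, contralateral breast, spinal cord, liver, stomach);
substitute published values for substantive analyses.

## The synthetic cohort generator

`generate_cohort()` gives every stage a reproducible input with known
ground truth.  Its defaults emulate the study conditions of the matched
breast-cancer comparison the package targets:

* **Covariate marginals** follow the unmatched baseline table of that
  population: age ~ truncated normal (mean 52, SD 11, range 28-75), AJCC
  stage probabilities (0.59, 0.17, 0.24), SCF irradiation 41%,
  chemotherapy 57%, T- and N-stage marginals to match.
* **Treatment assignment** is a logistic model on the covariates
  (intercept 0.575 for a ~64% VMAT share at baseline; coefficients make
  VMAT patients younger, lower-stage, less often SCF-irradiated and less
  often chemotherapy-treated).  A `confounding` multiplier scales the
  covariate effects; 0 gives a randomized-like cohort.  Because
  assignment is per patient, realized arm sizes vary around `n_per_arm`.
* **DVHs** per organ are normalized logistic survival curves in dose with
  modality-dependent location and scale (VMAT: smaller ipsilateral-lung
  volumes across the dose range, slightly larger low-dose spread in the
  contralateral lung and breast), plus per-5-Gy-band log-normal density
  perturbations (`band_sigma`, default 0.6 for the ipsilateral lung).
  The perturbations emulate plan-to-plan DVH shape variability.  They are
  not cosmetic: on a purely two-parameter smooth family, neighbouring
  V~x~ metrics are collinear at ~0.99 and *no* selector could single out
  a specific threshold; with them, adjacent correlations drop to roughly
  0.9, which is what makes dominant-factor selection a meaningful
  exercise — as it evidently is on real planning data.
* **Outcomes**: `P(grade >= 1 RP)` follows the LKB model on the realized
  ipsilateral-lung V40 with ground truth `TV50 = 15.07`, `m = 0.62` (the
  fitted values of the emulated study); grades 1:3 split 20:9:2 among
  events, echoing the matched cohort's grade distribution.  The
  generating factor is configurable so selection can be stress-tested
  against alternative truths.

What the generator does *not* emulate: spatial dose information (only
DVHs), inter-organ dose correlations beyond modality, longitudinal
grading, symptomatic-vs-radiographic endpoint distinctions, and censoring
or follow-up structure.  Passing tests therefore demonstrate correctness
of the estimators under the stated generative model, not clinical validity
on real cohorts.

## Numerical choices and degenerate inputs

* Cumulative curves must start at `V(0) = 100` and be non-increasing;
  files violating this are rejected with the offending row named.
* A cumulative curve that has not reached 0 at its last dose point has
  the residual volume assigned to one trailing bin on conversion to
  differential form.
* LKB fits reject all-identical factor values (TV50 unidentifiable) and
  single-class outcomes; boundary estimates raise a warning.
* Constant predictor columns are dropped from the LASSO with a warning;
  `lambda >= lambda_max` returns the exact null model.
* The matching caliper multiplier must be positive; empty pair lists make
  balance diagnostics an error rather than a silent empty table.
* The pipeline derives per-stage seeds from the global seed by fixed
  offsets (+101 synthesis, +202 folds, +303 fit restarts), so any stage
  can be re-run in isolation reproducibly.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the emulated study's size (32
per arm) and checks statistical properties at larger sizes chosen for
stable assertions: parameter recovery at n = 2000, profile-CI coverage
over 100 replicates of n = 250, selection stability over 50 replicates of
n = 300, and null-distribution checks with 400 simulated datasets.

## Known limitations

* The LKB implementation is the `n = 1` single-factor special case; free
  volume parameters and DVH-reduction schemes are out of scope.
* Bootstrap confidence intervals are not provided (profile likelihood
  only).
* The SCR layer implements the full carcinoma parameterization with its
  two R-limits; sarcoma models, dose-rate effects and relative-risk (ERR)
  formulations are out of scope.
* DICOM-RT parsing is out of scope; DVHs enter through the documented
  CSV dialect.
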