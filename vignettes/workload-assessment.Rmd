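---
title: "Preoperative workload assessment by linear discriminant analysis: methods"
author: "surgworkload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preoperative workload assessment by linear discriminant analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgworkload)
```

## The problem and the data model

Operative time in hand-assisted laparoscopic donor nephrectomy varies
several-fold between donors, driven largely by the amount and quality of
perinephric fat and by renal arterial anatomy. The package predicts,
before surgery, whether a donor will be a *heavy-workload* (difficult)
or *moderate-workload* (easy) case, from 16 candidate predictors
measured preoperatively: sex (1/0), age (years), body weight (kg), body
height (cm), total protein and albumin (g/dL), triglyceride and total
cholesterol (mg/dL), the renal artery count of the procured kidney, three
perinephric-fat thicknesses (mm), perinephric fat area (cm²) and mean CT
attenuation (negative for adipose tissue), and subcutaneous-fat
thickness (mm) and area (cm²). `variable_registry()` pins the canonical
names, units and published aliases; cohorts travel as validated
data.frames (`as_cohort()`, `read_cohort()`), and records with any
missing predictor are rejected from model fitting rather than imputed.

## Dichotomization

Workload is dichotomized on operative time with an inclusive rule:
difficult iff time ≥ threshold, 210 min by default. That boundary is the
84.1th percentile of the development cohort; 84.1% is the mass of a
normal distribution below its mean + 1 SD (`pnorm(1)` = 0.8413), so the
rule flags roughly the worst sixth of cases. Percentiles, where needed
(threshold sweeps), use linear interpolation between order statistics
(`stats::quantile` type 7); the convention is fixed and only affects the
sweep module, since the primary analysis uses the fixed minute value.

## The discriminant rule

The classifier is the normal-based linear discriminant rule: two
Gaussian classes with a shared covariance. From group means
$\mu_0, \mu_1$, shared covariance $\Sigma$ and priors
$\pi_i = n_i/(n_0+n_1)$ taken from the observed group sizes, the
discrimination index of a donor $x$ is

$$\Omega(x) = \log\frac{\pi_1}{\pi_0}
  - \frac12\left\{\Delta(x;\mu_1,\Sigma) - \Delta(x;\mu_0,\Sigma)\right\},
  \qquad \Delta(x;\mu,\Sigma) = (x-\mu)^\top \Sigma^{-1} (x-\mu).$$

$\Omega > 0$ predicts difficult; $\Omega = 0$ (a measure-zero event) is
assigned easy, a fixed tie rule chosen for determinism. $\Omega$ doubles
as a continuous severity score. The rule is affine-invariant, so no
standardization is applied (and none is needed).

Two estimators of $\Sigma$ are offered because the verbal description
of "the covariance matrix of all the feature vectors from both groups"
is ambiguous:

* `pooled` (default) — the pooled within-group covariance
  $[(n_0-1)S_0 + (n_1-1)S_1]/(n_0+n_1-2)$, the standard choice in
  discriminant analysis; and
* `total` — the covariance of all feature vectors combined, ignoring
  group structure.

Both are exposed everywhere (`covariance =`), and the
`scripts/reproduce_published.R` driver prints results under either mode
so users with the original development data can determine which one the
published tables used. A singular covariance is an explicit error that
names the offending subset — never a silent pseudo-inverse; an optional
ridge term `ridge * I` (default 0) is available for deliberately
degenerate synthetic tests. Numerically, a Cholesky factor whose
diagonal spans more than about 7 orders of magnitude is treated as
singular, which catches exact duplicates and constant columns that
floating-point pivots would otherwise let through.

Predictions against true labels form the conventional 2×2 table
(A = predicted difficult & difficult, B = predicted difficult & easy,
C, D analogous), from which five rates are reported as percentages:
HRDC = A/(A+B) (how often a "difficult" call is right), HREC = D/(C+D),
sensitivity A/(A+C), specificity D/(B+D), and the total hit rate
(A+D)/n. A rate with a zero denominator is reported as undefined (`NA`),
not as 0 or 100. Internally the rates are kept at full precision and
rounded only for display.

## Exhaustive subset search

With 16 candidates there are $2^{16}-1 = 65{,}535$ non-empty predictor
subsets — small enough to evaluate exhaustively, so no heuristic search
is used. `search_subsets()` encodes subsets as bit masks over the
registry order and exploits the fact that the (pooled or total)
covariance of any subset is a submatrix of the full-panel covariance:
the sufficient statistics are computed once and each subset costs one
Cholesky factorization plus two vectorized quadratic forms. The full
search over a 128-donor cohort takes a few seconds on one CPU.

The *best-apparent tier* is defined two ways, both reported: subsets
producing the **identical 2×2 table** as the best subset (the strict
definition), and the looser set of all subsets attaining the maximum
total rate. Singular subsets are recorded with a status, never silently
dropped, and the output is emitted in ascending mask order so identical
inputs give byte-identical tables.

## Estimating the true hit rates

Apparent (training-data) rates are optimistic. Two corrections are
implemented:

**Leave-one-out cross-validation.** Each donor is classified by a rule
fitted to the other $n-1$; the $n$ held-out predictions pool into one
2×2 table. "Conventional cross-validation" is interpreted as
leave-one-out — the standard in the discriminant-analysis literature —
deliberately avoiding a fold count as a free parameter, and making the
estimate fully deterministic. Internally each fold reuses the full-data
sufficient statistics through an exact rank-one downdate of the group
mean and scatter (not an approximation; the test suite checks it against
naive refits).

**The .632 bootstrap.** `n_boot` resamples of size $n$ are drawn with
replacement; the rule is fitted on each and applied to the out-of-bag
donors only; out-of-bag predictions are pooled across replicates into a
single table, and each rate is combined as
$r_{.632} = 0.368\,r_{app} + 0.632\,r_{oob}$. Pooling out-of-bag
predictions before computing rates (rather than averaging per-replicate
rates) is a deliberate choice: with only ~21 difficult donors, single
replicates often contain too few out-of-bag difficult cases for stable
per-replicate rates. The default `n_boot = 200` follows classic .632
practice; the acceptance script uses 1000 for its headline estimate. A
resample must contain at least `min_group = 2` donors per class (a rule
is unfittable otherwise); violating resamples are redrawn and counted,
with a hard attempt limit. The seed is mandatory and the caller's RNG
stream is left untouched.

**The selection funnel** (`select_final_model()`) chains the published
three-stage pipeline: (1) exhaustive search, keep the best-apparent
tier; (2) LOOCV on the tier, keep subsets within `cv_band` percentage
points of the best CV total (default 1.6, the band that separates the
published 28 stage-2 survivors from the rest on the development data);
(3) .632 on the survivors, winner by highest .632 total, ties broken by
fewer variables then mask order.

## Threshold adequacy

`sweep_thresholds()` re-runs the evaluation with the boundary at each
percentile of a grid (default 2nd–98th, step 1) to show that the
conclusions are not an artifact of the 84.1th-percentile choice.
Thresholds whose dichotomy cannot be fitted (a group below 2 donors, or
a singular covariance) are reported as skipped rather than interpolated.

## Association statistics

Supporting analyses delegate to the standard implementations: OLS via
`lm` (univariate per predictor, and all 16 jointly — no stepwise
selection, matching the published single multivariate column),
correlations via `cor.test` (Spearman with average ranks on ties),
Mann-Whitney U via `wilcox.test` (exact for small tie-free samples, else
normal approximation with tie correction) for the extreme-workload
comparison (≥ 240 min vs ≤ 100 min by default), and Fisher's exact test
via `fisher.test` — the Freeman–Halton r×c extension for the
fat-area-quartile complication table, with a seeded Monte-Carlo fallback.
No multiple-testing correction is applied (none is described for the
original analyses). Complication grades use the modified Clavien scale
encoded as ordered ranks 0 < 1 < 2a < 2b < 3a < 3b < 4; grade 0 donors
are included in rank correlations.

## The synthetic cohort generator

`simulate_cohort()` exists so that every other module is testable
without patient data. It emulates the development cohort's statistical
shape:

* marginal means, SDs and ranges of the 14 continuous variables match
  the published summary table (e.g. operative time 159.1 ± 47.4 min,
  fat area 14.39 ± 10.98 cm², fat attenuation −83.98 ± 12.17);
* sex is male with probability 58/128, via a latent-normal threshold so
  it can correlate with fat area;
* the renal artery count is categorical on 1–4 with probabilities
  (86, 32, 7, 3)/128;
* continuous variables are drawn from a correlated normal and truncated
  to the published ranges by rejection (resampling rows out of bounds,
  with a capped retry count);
* operative time is linear in the two generating variables —
  3.2 min/cm² of fat area and 21 min per renal artery, the magnitudes of
  the published univariate regression slopes — plus Gaussian noise,
  floored at 90 min.

The intercept (83 min) and noise SD (28 min) were calibrated
analytically, once, from the target moments: with
$E[\text{area}] = 14.39$ and $E[\text{RA}] = 1.43$ the linear part
contributes a mean of ~76 min (hence intercept ≈ 83 for a 159-min mean)
and a variance of ~1450 min², leaving
$\sqrt{47.4^2 - 1450} \approx 28$ min for the noise so the total SD
matches. This puts about 14–16% of donors at or beyond 210 min, matching
the development cohort's 21/128.

Default cross-correlations (weight–height 0.6, weight–subcutaneous-area
0.5, 0.6 within the perinephric block, area–attenuation −0.4,
male–fat-area 0.3) are plausibility choices, clearly exposed in
`cohort_config()`, not claims about the real cohort — the true
inter-variable correlations were never published. The correlation map is
repaired to the nearest positive-definite matrix when a user
configuration requires it, with a message.

What the generator does **not** reproduce: the right-skew of
triglyceride and fat area (it uses truncated normals, so its tails are
lighter); the exact joint dependence structure; and any row of the real
data. Because rows are rejected jointly, variables correlated with a
heavily truncated partner (the perinephric block) sit up to ~0.15 SD
away from their nominal means — the test suite checks marginals against
truncated-normal oracles with exactly that allowance. Consequently,
passing tests demonstrate that the *pipeline* behaves correctly under
realistic signal and noise, not that any particular hit rate will be
attained on real donors.

`simulate_complications()` adds modified-Clavien grades at a 9.4%
overall rate (grades 1/2a/2b at 6:4:2), with a weak log-odds dependence
on subcutaneous fat and independence from the workload index — the
pattern seen in the development cohort, where complications tracked
wound-related factors but not predicted workload.

## Problem sizes and reproducibility

The test suite and acceptance script run entirely on synthetic data at
the study scale: cohorts of n = 128, the full 65,535-subset search,
LOOCV over the resulting tier, .632 with B = 200 (B = 1000 for the
acceptance script's headline estimate), and 20-seed replications for the
calibration and recovery properties. These sizes keep a full run in the
minutes range on one CPU while exercising every code path at realistic
dimensions. All stochastic steps take explicit integer seeds; bootstrap
and generator functions restore the caller's RNG state.

Model files are JSON with 17 significant digits (reparsing is
bit-identical), and cohort CSVs print doubles as `%.17g` for the same
reason.

## Known limitations

* The rule assumes two Gaussian classes with a shared covariance;
  strongly non-elliptical predictors (e.g. raw triglyceride) are used
  as-is, as in the original analysis, which may cost some efficiency.
* With ~21 difficult donors, HRDC and sensitivity estimates carry large
  Monte-Carlo and sampling uncertainty; the total hit rate is the most
  stable of the five.
* The exhaustive search tie tier can be large when the signal
  concentrates in a couple of correlated variables; the funnel's later
  stages, not the tier size, carry the selection burden.
* Whether the published shared covariance was pooled-within or total is
  undetermined without the deposited data; the package defaults to
  pooled and exposes both.
* The development-cohort context (single operator, left-sided
  procedures, a relatively lean population) travels with any rule built
  from such data; the package builds cohort-specific rules rather than
  claiming a universal one.
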