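---
title: "Normative modelling of hippocampal volumetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of hippocampal volumetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippnorm)
```

## The problem

Automated segmentation tools turn a T1-weighted MRI into left and right
hippocampal volumes in mm³. Whether such a volume is *abnormal* for a given
person depends on their age and head size: hippocampi shrink through late
adulthood, and larger heads carry larger hippocampi. Normative modelling
answers the question "where does this volume sit among cognitively normal
people of the same age?" by estimating age-conditional percentile curves
from a reference population and flagging volumes below the 5th-percentile
curve as atrophic.

`hippnorm` implements the full chain: head-size normalization, residual
family selection, age-conditional percentile estimation, single-case
classification, and the validation battery (coverage calibration,
between-tool agreement, diagnostic accuracy). This vignette documents the
statistical model, the tunable parameters and their defaults, the numerical
choices, what the synthetic generator does and does not emulate, and the
package's known limitations.

## Head-size normalization

The proportional method rescales each volume to a fixed reference
intracranial volume:

$$\mathrm{HV}_{norm} = \frac{\mathrm{HV}}{\mathrm{TIV}} \times 1409\ \mathrm{ml}.$$

The reference of 1,409 ml (`normalization_config()`) is applied identically
to FreeSurfer eTIV and SPM-derived TIV sources; the TIV *source* and *unit*
are explicit record metadata so downstream analyses can stratify by them.
Units are never auto-detected — an eTIV in mm³ and a TIV in ml differ by
three orders of magnitude, and a silent heuristic that guesses wrong corrupts
every percentile downstream. The internal canonical unit is mm³
(1 ml = 1000 mm³). Only the ratio method is offered; covariate-regression
TIV adjustment is a different estimand and deliberately out of scope.
Normalization is exactly the identity at the reference TIV (the scale factor
is computed as a ratio first, so it is 1.0 in floating point), degree-1
homogeneous in the volume and degree-(−1) in the TIV. TIVs outside a
plausible 800–2,200 ml window are flagged with a warning but still
processed: record-level review, not silent exclusion.

## Residual families

Two families are first-class:

* **Gamma**, parameterized by mean $\mu$ and dispersion $\sigma$ equal to the
  coefficient of variation (shape $= 1/\sigma^2$). FreeSurfer-like volume
  distributions are mildly right-skewed, which the gamma captures; the mean
  parameterization is what makes a log link on the location natural.
* **Logistic**, by location and scale — symmetric with heavier-than-normal
  tails, typical of machine-learning segmentations.

The log-normal is available as a sanity alternative in family ranking.
Single-family fits (`mle_fit()`) are maximum likelihood via
`fitdistrplus`; the fitted object carries the attained log-likelihood and
the number of fitted parameters, which the goodness-of-fit test needs.

`rank_families()` reproduces the family-search step: each candidate is
fitted, scored by AIC (primary key; reproducible and penalizing parameter
count — the historical "best fit" criterion in this literature is typically
left unspecified), with the chi-square goodness-of-fit p-value reported
alongside and used only to break AIC ties. Whether selection is run on raw
volumes, normalized volumes, or age-detrended residuals is left to the
caller — all three are legitimate and answer slightly different questions;
the package takes a numeric vector and does not decide for you.

`chi2_gof()` uses cells of *equal probability* under the candidate
distribution (default 10), so every cell has expected count $n/10$ and no
cell is starved in the tails. Degrees of freedom are
$b - 1 - k$ with $k$ the number of estimated parameters. Two caveats are
documented rather than hidden: with parameters estimated by full-sample MLE
(not from the binned counts) the null distribution of the statistic lies
between $\chi^2_{b-1-k}$ and $\chi^2_{b-1}$, so the test is slightly
conservative-to-liberal depending on the family; and cells whose expected
count drops below 5 are merged with a warning and the degrees of freedom
adjusted.

## The age-conditional model

`fit_normative()` estimates, by direct maximum likelihood,

* Gamma: $\log \mu(\mathrm{age}) = \beta_0 + \beta_{age}\,\mathrm{age}$,
  constant $\sigma$;
* Logistic: $\mathrm{location}(\mathrm{age}) = \beta_0 +
  \beta_{age}\,\mathrm{age}$, constant scale.

A linear location with constant dispersion is the minimal model consistent
with a single reported per-year slope on log-transformed volumes, and it
cannot produce crossing percentile curves (an invariant re-asserted after
every fit). Richer location/scale/shape machinery — P-spline smoothers,
age-varying dispersion — is intentionally **not** offered, not even behind a
flag: a smoother fitted to a few hundred subjects invites exactly the kind
of wiggly, non-monotone norm that single-case classification should not
stand on, and offering it as an option would imply the package validates it.
Users who need smooth-location models have `gamlss`/`mgcv`-class tooling;
the model here is a declared approximation, not a claim about what any
particular historical fit did.

Numerical choices:

* the age covariate is centred internally before optimization — over an
  adult age range the raw intercept (volume at age 0) is nearly collinear
  with the slope and stalls quasi-Newton methods; estimates are
  back-transformed, so the reported $\beta_0$ is on the uncentred scale;
* deterministic initialization from least squares on the (log) volumes and
  moment estimates of dispersion; no random restarts, so fits are exactly
  reproducible;
* BFGS on $(\beta_0^{c}, \beta_{age}, \log \sigma)$ with a value-change
  tolerance of 1e-14, the observed-information covariance from the final
  Hessian, and the residual gradient norm stored in the model's convergence
  diagnostics;
* preconditions: at least 50 complete records and an age span of at least
  10 years — below that an age-conditional norm is not identified and the
  fit refuses rather than extrapolating a slope from noise;
* a fitted positive age slope is legal but warns: it violates the expected
  monotone decline and usually indicates a selection artefact in the input
  cohort.

In tests, the Gamma mean-model coefficients are cross-checked against
`stats::glm(family = Gamma(link = "log"))`, which is an independent oracle
for $(\beta_0, \beta_{age})$ because the gamma GLM score equations for the
mean do not involve the shape parameter.

### Derived quantities

* `predict_quantile()` — the percentile curve: family quantile at the
  age-specific location. Ages outside the fitted range error unless
  `extrapolate = TRUE` (then warn); tabulation (`make_threshold_table()`)
  tolerates a one-year grace beyond the observed range, since cohorts
  rarely sample their nominal age endpoints exactly.
* `make_threshold_table()` — the age-by-level threshold table, default grid
  56–90 years by the seven conventional levels {5, 10, 25, 50, 75, 90, 95},
  rounded to integer mm³ by default (the resolution at which such norms are
  reported; `digits = NULL` keeps full precision). Grid and rounding are
  configurable because the right choices are a reporting convention, not a
  statistical one.
* `expected_volume()` — the model *median* by default: it is link-free,
  percentile-consistent (it is exactly the 50th curve), and robust to the
  mild skew of the gamma; the mean is available via `type = "mean"`.
* `subject_percentile()` / `flag_abnormal()` — single-case classification.
  Abnormality uses *strict* inequality (volume < cutoff): thresholds are
  phrased as "below x mm³", so an exact tie is not abnormal. Classification
  against the packaged published anchors requires an anchored age; anchors
  are never interpolated, because inventing intermediate "published" values
  would misrepresent their source. Intermediate ages require a fitted model.
* `coverage_check()` — per-level observed fraction strictly below the curve
  with a 1-df chi-square against the nominal level, and the maximum
  discrepancy in percentage points; `compare_real_vs_computed()` — mean
  observed-minus-expected difference with t-based 95% CI, the operational
  test that an external cohort matches the norms.

`diagnostic_metrics()` requires the caller to supply the reference-standard
truth labels explicitly. Published accuracy tables in this area are often
ambiguous about what "truth" meant (agreement with a second tool? an
empirical cohort quantile?); the package refuses to guess, and reports
undefined ratios (zero denominators) as `NA`, never as 0.

## The synthetic generator

`generate_cohort()` emulates the statistical structure the analysis assumes,
so that every stage — including failure handling — is testable without
restricted data. What it emulates, with defaults:

| feature | default | rationale |
|---|---|---|
| ages | uniform on 56–90 y | the age support of the reference norms |
| family | Gamma, log link | FS-like residual behaviour |
| $\beta_{age}$ | −0.008 / y (log scale) | reported FS left-hemisphere decline |
| $\beta_0$ | median ≈ 3,600 mm³ at 74 y | FS-scale volumes |
| dispersion | CV 0.11 | ≈ 374/3,530, the CN mean-to-SD ratio |
| group shifts | CN 0, MCI −349, AD −658 mm³ | CN−MCI and CN−AD mean differences of a typical validation cohort, applied on the volume scale because that is the scale those means are reported on |
| right − left | +100 mm³ | right hippocampi run larger; magnitude from typical CN means |
| TIV | normal(1,409, 120) ml, truncated ±3 SD | centred on the normalization reference; the spread is a package choice sized to exercise normalization, as no reference spread is published |
| outliers | rate 0 (off); factors ×0.4 / ×2.5 | gross under/over-segmentation; prevalence of real QC failures is not quantitatively published, so the injector's defaults are illustrative |

The AA-like configuration used in tests and the acceptance script places a
*logistic* distribution on the **log**-volume scale with slope −0.004/y and
scale $0.11\sqrt{3}/\pi$ (so the log-scale SD matches the FS CV), median
≈ 5,000 mm³ at 74 — AA-like tools read roughly 1.4× higher than FS-like
ones.

Volumes are drawn by inverse CDF at a uniform generating percentile, which
is recorded per subject in a ground-truth sidecar (`hn_truth()`); the
normalized-scale draw is then *de-normalized* through the subject's TIV, so
that `normalize_cohort()` recovers the generating distribution exactly and
the full loop (generate → normalize → fit → coverage) closes. All
randomness flows from the mandatory `seed`; the caller's RNG state is saved
and restored.

`generate_paired_tools()` couples two tools through a Gaussian copula: a
shared latent normal deviate plus tool-specific noise gives each subject a
generating percentile under each tool; the latent correlation dials
expected flag agreement from independence (κ ≈ 0) through the moderate
agreement seen between real tools (κ ≈ 0.5) to identity (κ = 1).

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: scanner/field-strength/vendor effects, sex
differences, non-linear age trajectories, spatially correlated segmentation
error, longitudinal within-subject correlation, and the selection processes
of real observational cohorts. Tests against synthetic cohorts verify that
the *estimators are correct under the stated model*, not that the model is
true of any particular scanner population.

## Problem sizes and test design

The simulation scales mirror the study design the package targets: fitting
cohorts of n = 532 (FS-like) and n = 421 (AA-like), 200-replicate
parameter-recovery sweeps, and 50,000-draw evaluation cohorts for coverage
calibration (binomial SE ≈ 0.1 pp at the 5% level). Stochastic assertions
are tied to explicit sampling distributions — exact binomial intervals for
coverage counts, 3-SE bands for recovered means — rather than ad-hoc
tolerances, and every stochastic test fixes its seed. One deliberate case:
the in-sample "max coverage discrepancy < 3 pp" property holds in about 95%
of replicates by construction, so it is asserted as a one-sided binomial
bound on the failure rate rather than as a point threshold that would fail
one run in two.

## Degenerate inputs and edge policies

* `read_cohort()` never fails globally on a bad row: rows with missing or
  unparseable age, missing both volumes, or non-positive volumes are set
  aside with machine-readable reasons (`hn_rejected()`); accepted + rejected
  always account for every data row.
* Zero-variance samples refuse to fit; cohorts with an age span under
  10 years refuse an age-conditional model; single-subject comparisons
  refuse a CI.
* Kappa with degenerate marginals ($p_e = 1$) is 1 under perfect agreement
  and an error otherwise — there is no meaningful chance correction.
* Percentile tables enforce strictly increasing thresholds in level at
  construction and again before writing; a violation names the offending
  (age, level) pair.

## Known limitations

Constant dispersion and a linear location are approximations; real
dispersion may drift with age, and decline may accelerate in late life. The
norms carry no covariates beyond age — sex, field strength and vendor are
deliberately excluded (their reported influence on TIV-corrected hippocampal
volume is modest, and adding them changes the estimand of the norm). The
published anchors ship only at the printed (age, level) points, so
single-case classification against them is limited to those ages. Finally,
synthetic validation bounds estimator behaviour under the generator's
assumptions only; transferring fitted norms to a new population still
requires the external checks the package provides (`coverage_check()`,
`compare_real_vs_computed()`, group percentile summaries) run on that
population's data.
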