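---
title: "How many visual fields are needed to predict the central 10 degrees?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many visual fields are needed to predict the central 10 degrees?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vftrend)
```

## The question

In glaucoma, damage to the central 10 degrees of the visual field determines
reading, face recognition and quality of life, so clinicians monitor it with
the Humphrey 10-2 test: 68 locations spaced 2 degrees apart, each reporting a
light sensitivity between 0 and 40 dB. Management decisions hinge on
forecasting each location's sensitivity a few visits ahead ("point-wise trend
analysis"), usually by ordinary least-squares linear regression (OLSLR) of
sensitivity on time. Two practical questions follow:

1. **How many past tests are needed** before the forecast stops improving?
2. **Do nonlinear trend models help?** Sensitivity decay need not be linear,
   and the instrument floor at 0 dB suggests curvature.

`vftrend` implements a complete, reusable version of this evaluation: five
per-location trend models, a rolling prediction-error experiment at one-,
two- and three-test-ahead horizons, a saturation rule for "number of tests
required", mixed-model significance testing, and a synthetic cohort
generator that emulates the severe, slowly progressing open-angle-glaucoma
population on which such analyses are typically run (since clinical series
of this length are rarely shareable).

## Trend models

At each location, with `x` the time in years since the first retained test
and `y` the sensitivity in dB, the candidate models are

| model | formula | fitted by |
|---|---|---|
| OLSLR | `y = a x + b` | closed-form normal equations |
| exponential | `y = exp(a x + b)` | nonlinear LS in dB space |
| quadratic | `y = a x^2 + b x + c` | closed-form polynomial LS |
| M-robust | `y = a x + b`, Huber loss | IRLS |
| logistic | `y/40 = 1 / (1 + exp(a x + b))` | nonlinear LS on the 0-1 scale |

Design choices where the procedure was genuinely open:

* **Fitting criterion for the nonlinear models.** Both are fitted by least
  squares in the observation space (dB for the exponential; the 0-1 scale for
  the logistic, whose predictions are rescaled by 40), by Levenberg-Marquardt
  iterations started from a straight-line fit of the log- or logit-transformed
  responses. The transform is only used for initialization (scaled values are
  clamped to `[0.01, 0.99]` so the logit is finite at 0 and 40 dB); the
  objective uses the untransformed data. If the optimizer fails the
  initializer fit is returned, flagged `converged = FALSE`. This makes all
  five models comparable: each minimizes squared error on the measurement
  scale, deterministically.
* **Robust regression recipe.** Huber loss with tuning constant `k = 1.345`
  (95% Gaussian efficiency) and scale re-estimated each iteration as
  `MAD(residuals about 0)/0.6745` — the de-facto standard M-estimation
  recipe. Iteration starts at OLS and stops at a maximum coefficient change
  below `1e-8` or 100 iterations. If the scale collapses (at least half the
  residuals exactly zero) the OLS fit is returned: with no measurable noise
  there is nothing to robustify. On small series with one gross outlier this
  iteration can approach its solution slowly and report `converged = FALSE`;
  the reference implementation (`MASS::rlm`) behaves identically, and the
  fitted slope is still strictly closer to the generating trend than OLS.
* **Prediction clamping.** Fitted lines can leave `[0, 40]` dB. Clamping is
  available (`clamp = TRUE`, or `--clamp-predictions` in the CLI) but off by
  default: unclamped errors preserve differences between models, and the
  bounded models (exponential, logistic) respect the range without help.

## The rolling prediction experiment

Series are prepared by dropping unreliable tests (more than 20% fixation
losses or more than 15% false positives — strictly "more than", so boundary
tests are kept), retaining the first 13 reliable tests, and rebasing time to
the first retained test. Eyes with fewer than 13 reliable tests are excluded.
Where an eye has reliable tests beyond the thirteenth they are ignored
(filter-then-truncate; the alternative reading — excluding eyes with any
unreliable test — would discard data for no statistical benefit).

For horizon `h` (1, 2 or 3 tests ahead), windows run from 5 tests (shorter
series are known to predict poorly) up to `13 - h`: using tests `1..n`, test
`n + h` is predicted at its actual acquisition time; the point-wise mean
absolute error (MAE) is the unweighted mean of the 68 absolute errors —
every location counts, including those at the floor. The mean sensitivity
(MS) path fits the same model to the per-test MS series and records the
absolute error of the predicted MS. That gives 8, 7 and 6 windows per eye
at horizons 1, 2, 3.

Per cell (model, horizon, window length), per-eye errors are summarized as
mean, SD (denominator `n - 1`) and a normal-approximation 95% CI of the mean
(`mean ± 1.96 SE`). The CI deliberately ignores the correlation between two
eyes of one patient; formal comparisons use the mixed model below, and the
CI's role is only to define saturation:

* **Saturation rule.** The best window is the one with the smallest mean
  error (ties toward the longest series, which is where the error settles);
  the *number of tests required* is the smallest window whose mean error
  falls at or below the best window's CI upper bound. "At or below the upper
  bound" rather than "inside the interval" because the error approaches its
  minimum from above. A `1e-10` dB absolute guard makes exact-arithmetic
  cohorts (all errors zero) saturate immediately instead of comparing
  rounding noise.
* **Subgroups.** Severity splits at an initial mean deviation (MD) of
  −20 dB and progression at an MD slope of −0.25 dB/year; boundary values go
  to the less severe group (the thresholds are stated as strict inequalities
  on both sides, leaving the boundary undefined — some convention is needed
  and this one is conservative).
* **MD analogue.** The instrument's weighted, age-corrected MD is
  proprietary. The package uses the unweighted mean of total deviations
  against a configurable normative grid (default: flat 33 dB; within the
  central 10 degrees the eccentricity dependence of normal sensitivity is
  small). Only MD ordering and slopes enter any analysis, and both are
  invariant to the reference level.

## Model comparison

Per cell, the candidate model's per-eye errors are compared with OLSLR's in a
linear mixed model: response = per-eye error in long format (two rows per
eye), fixed effect = candidate-model indicator, random intercept per
*patient*, absorbing the correlation between fellow eyes. The p-value is the
Wald-type t-test of the indicator with Satterthwaite degrees of freedom; in
the balanced one-eye-per-patient case this reduces to a paired t-test (a
property the tests verify to `|Δp| ≤ 0.01`). Benjamini-Hochberg correction
is applied within each family — one family per (horizon, analysis path,
subgroup), pooling all candidate models and window lengths, mirroring one
results table per horizon — and significance is an adjusted p below 0.05.

## The synthetic cohort generator

`generate_cohort()` emulates the population such analyses target: 180 eyes of
133 patients (47 bilateral), 13 reliable tests per eye about 0.625 years
apart (7.5 years of follow-up over 12 intervals), initial MD −19.8 ± 8.1 dB,
MD slope −0.33 ± 0.40 dB/year. All constants are configuration
(`synth_config()`), not code. Mechanisms, in generation order:

* **Paired eyes.** Patient-level severity and progression factors give
  fellow eyes a correlation of 0.5 (configurable; real within-patient
  correlation is not well established) via a Gaussian copula.
* **Baseline fields.** The initial MD target is drawn from a normal
  truncated to `[−33, 0]` dB whose proposal mean is calibrated so the
  truncated mean equals the configured mean (naive truncation would shift
  the realized cohort about +0.7 dB). The baseline field is the normative
  level plus a spatially correlated defect (squared-exponential kernel,
  4-degree correlation length, 7 dB marginal SD — deep focal defects with
  smooth borders), shifted by root-finding so the clamped (`[0, 35]` dB)
  field hits the MD target exactly.
* **Progression.** Decline is allocated across locations in proportion to
  remaining sensitivity — severe eyes progress on their surviving island,
  since a floored location cannot lose more — plus a spatially correlated
  per-location perturbation (SD 0.2 dB/year). The allocation is scaled per
  eye (root-finding, on the branch before the deepest expressible decline)
  so that the OLS slope of the *floored* true MD trajectory over the eye's
  actual schedule equals its target rate, and the latent rate distribution
  is shifted once per cohort so the expressible mean equals the configured
  mean. Without these steps the hard floor makes the realized cohort roughly
  25% less progressive than configured; the configured moments describe the
  measured cohort, which is how such values are reported. Eyes whose target
  outruns what their residual field can express are capped at their deepest
  expressible decline — also true of real eyes.
* **Noise and censoring.** Test-retest noise is Gaussian with an SD that
  interpolates linearly in true sensitivity from 1.5 dB at 35 dB to 4 dB at
  0 dB — the simplest mechanism reproducing the greater variability of
  damaged locations (central-field variability is lower than peripheral,
  hence the moderate ceiling value). Measurements are censored into
  `[0, 40]` dB and rounded to integers as the instrument reports. True
  trajectories are floored at 0 (progression stops at the floor); linear
  truth is the default, with exponential and logistic shapes available for
  misspecification studies.
* **Reliability.** The schedule of *reliable* tests is drawn first
  (intervals `N(0.625, 0.15)` years, truncated at 0.1), so the 13 retained
  tests span the configured follow-up; unreliable tests (violating the
  fixation-loss or false-positive threshold) are then inserted into
  inter-test gaps at rate 0.05. Thinning a single visit stream instead would
  stretch the retained series beyond the intended follow-up.

A `truth` record (per-eye and per-point baselines, slopes and labels)
accompanies every cohort for parameter-recovery testing.

### What passing tests do and do not show

The generator reproduces the *statistical structure* the analysis assumes —
trend plus heteroscedastic censored noise, paired eyes, realistic
demographics — and the package's tests show the pipeline recovers known
truth and reproduces the qualitative behavior expected on such data
(error falling with window length, rising with horizon, quadratic overfit of
short windows). It does not emulate staircase psychophysics, learning and
fatigue effects, long-term fluctuation beyond the noise model, media
opacity, or measurement-date clustering; absolute error magnitudes on real
series may differ, so clinical conclusions should rest on clinical data.

## Numerical choices and degenerate inputs

* Window fits require at least 2 (3 for quadratic) distinct times; a
  constant-time design raises a singular-design error naming the location.
* All-zero series make the exponential model degenerate (error); the
  logistic model handles 0 and 40 dB via initializer clamping only.
* Evaluation cells with one eye keep their mean but report `NA` spread and
  CI; `find_saturation` requires all windows of a horizon and lists gaps.
* Mixed-model cells need at least 3 patients; singular variance estimates
  (common when the patient variance is ~0) are accepted — the test then
  approaches the paired/two-sample t-test it nests.
* Problem sizes in the test suite: oracle comparisons use 1,000 random
  instances; structural checks use the default 180-eye cohort averaged over
  5 seeds; null calibration uses 200 replicates of 4-cell families (40 eyes
  in 30 patients). These sizes give Monte-Carlo standard errors comfortably
  inside the asserted tolerances.

## Known limitations

* The saturation rule inherits the normal-approximation CI; with few eyes
  the "number required" is noisy.
* The generator's within-patient correlation, defect SD and correlation
  length are plausible rather than fitted to test-retest datasets.
* Only fixed-baseline prediction is implemented (the window always starts at
  test 1); re-baselining strategies are a different question.
* The 10-2 grid is the only supported pattern; 24-2/24-2C and summary
  indices beyond MS/MD analogues (VFI, pattern deviation) are out of scope.
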