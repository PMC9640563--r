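# vftrend

How many Humphrey 10-2 visual-field examinations does it take to predict the
next ones accurately?

In glaucoma, the central 10 degrees of vision are monitored with the 10-2
test: 68 locations on a 2-degree grid, each reporting a sensitivity in
0–40 dB. Clinicians forecast each location by regressing sensitivity on time
("point-wise trend analysis"). `vftrend` implements the full evaluation of
that practice:

* **Five per-location trend models** — ordinary least-squares linear
  regression (OLSLR, the reference), exponential `y = exp(ax + b)`,
  quadratic `y = ax² + bx + c`, Huber M-estimator robust linear regression
  (IRLS, `k = 1.345`, MAD/0.6745 scale), and logistic
  `y/40 = 1/(1 + exp(ax + b))`.
* **A rolling prediction-error experiment** — with the first `n` tests
  (`n = 5..13−h`), predict the test `n + h` ahead (`h` = 1, 2, 3) at every
  location; score each eye-window by the mean absolute error (MAE) over the
  68 locations, plus a mean-sensitivity (MS) path.
* **A saturation rule** — the *number of tests required* is the smallest
  window whose mean MAE reaches the 95% CI upper bound of the best
  (longest-window) OLSLR cell.
* **Formal model comparison** — per-eye errors compared with a linear mixed
  model (random intercept per patient, to respect fellow-eye pairing), with
  Benjamini–Hochberg correction per (horizon × path × subgroup) family at
  α = 0.05, and subgroup analyses split at initial MD −20 dB and MD slope
  −0.25 dB/year.
* **A synthetic cohort generator** — 180 eyes / 133 patients by default, 13
  reliable tests per eye over ~7.5 years, initial MD −19.8 ± 8.1 dB, MD
  slope −0.33 ± 0.40 dB/year, spatially correlated defects, floored
  trajectories, heteroscedastic censored test-retest noise, integer dB,
  unreliable tests (>20% fixation losses or >15% false positives)
  interleaved — with a full truth record for parameter-recovery testing.

## Worked example

Simulate a 60-eye cohort, run the horizon-1 experiment with the reference
and quadratic models, and ask how many tests are needed:

```r
library(vftrend)

cfg    <- synth_config(n_patients = 45, n_eyes = 60)
gen    <- generate_cohort(cfg, seed = 2026)
cohort <- prepare_cohort(gen$cohort, quiet = TRUE)

res <- run_experiment(cohort, models = c("olslr", "quadratic"),
                      horizons = 1, subgroups = FALSE)

subset(res$cells, analysis_path == "PW" & model == "olslr")
#>   model horizon n_used n_eyes mean_mae sd_mae ci_high
#> 1 olslr       1      5     60     3.29  0.569    3.44
#> 2 olslr       1      6     60     3.10  0.452    3.21
#> 3 olslr       1      7     60     3.00  0.424    3.11
#> 4 olslr       1      8     60     2.82  0.421    2.93
#> 5 olslr       1      9     60     2.77  0.443    2.88
#> 6 olslr       1     10     60     2.71  0.385    2.81
#> 7 olslr       1     11     60     2.70  0.377    2.79
#> 8 olslr       1     12     60     2.66  0.394    2.76

subset(res$saturation, analysis_path == "PW")
#>   horizon best_n_used best_mae ci_upper n_required
#> 1       1          12     2.66     2.76         10
```

Reading this: prediction error falls steadily as the fitting window grows
(3.29 dB with 5 tests down to 2.66 dB with 12), and from 10 tests onward the
mean MAE is already inside the best window's 95% CI — more tests stop
paying. The mixed-model comparison shows the quadratic model is
significantly *worse* than the straight line, drastically so for short
windows (it overfits and extrapolates its curvature):

```r
cmp <- compare_all(res, subgroups = FALSE)
subset(cmp, n_used %in% c(5, 12) & analysis_path == "PW")
#>   analysis_path subgroup horizon n_used     model estimate   p_raw p_adjusted significant
#> 1            PW  overall       1      5 quadratic     2.35 1.5e-26    6.0e-26        TRUE
#> 2            PW  overall       1     12 quadratic     0.54 5.4e-15    5.4e-15        TRUE
```

`estimate` is the mean MAE penalty in dB relative to OLSLR.

A thin command-line wrapper ships in `inst/cli/vftrend.R`
(`simulate` / `evaluate` / `compare` subcommands over the same functions),
and `cmd_evaluate()` writes the result tables plus MAE-versus-window figures
with the saturation bound as a dashed line.

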