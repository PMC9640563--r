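#' Enumerate fitting windows for a prediction horizon
#'
#' Prediction starts from a 5-test series: with the first `n_used` tests the
#' test `n_used + horizon` is predicted, and `n_used` runs from 5 up to
#' `n_total - horizon`. For a 13-test series this yields 8, 7 and 6 windows at
#' horizons 1, 2 and 3 (predicting the 6th..13th, 7th..13th and 8th..13th
#' tests respectively).
#'
#' @param horizon 1, 2 or 3: predict the first, second or third future test.
#' @param n_total Series length (default 13).
#' @param n_min Shortest fitting window (default 5).
#' @return A tibble with columns `n_used` and `target_index`.
#' @export
enumerate_windows <- function(horizon, n_total = 13L, n_min = 5L) {
  if (!horizon %in% 1:3) stop("`horizon` must be 1, 2 or 3", call. = FALSE)
  n_used <- seq.int(n_min, n_total - horizon)
  tibble::tibble(n_used = as.integer(n_used),
                 target_index = as.integer(n_used + horizon))
}

#' Rolling prediction errors for one eye
#'
#' For every window of the horizon, fits the model point-wise on tests
#' `1..n_used`, predicts each location at the target test's time, and compares
#' with the actual target test. The per-window point-wise MAE is the mean of
#' the 68 absolute errors. The mean-sensitivity (MS) path fits the same model
#' to the per-test MS series over the window and records the absolute error of
#' the predicted MS.
#'
#' @param series A prepared [vf_series()].
#' @param model One of [model_kinds()].
#' @param horizon 1, 2 or 3.
#' @param clamp Truncate predictions into `[0, 40]` dB?
#' @param keep_pointwise Keep the 68-vectors of predicted / actual /
#'   absolute-error values as list columns?
#' @return A tibble, one row per window: `eye_id, patient_id, model, horizon,
#'   n_used, target_index, mae, ms_predicted, ms_actual, ms_ae` (plus list
#'   columns `predicted`, `actual`, `pw_abs_errors` if requested).
#' @export
evaluate_eye <- function(series, model = model_kinds(), horizon = 1L,
                         clamp = FALSE, keep_pointwise = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(series, "vf_series"))
  windows <- enumerate_windows(horizon, n_total = n_tests(series))
  ms <- ms_series(series)
  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    n_used <- windows$n_used[i]
    target <- windows$target_index[i]
    t_target <- series$time_years[target]
    pw <- fit_pointwise(series, n_used, model)
    predicted <- predict(pw, t_target, clamp = clamp)
    actual <- series$sens[target, ]
    abs_err <- abs(predicted - actual)

    idx <- seq_len(n_used)
    ms_y <- ms[idx]
    ms_fit <- fit_model(series$time_years[idx], ms_y, model)
    ms_pred <- predict(ms_fit, t_target, clamp = clamp)

    row <- tibble::tibble(
      eye_id = series$eye_id, patient_id = series$patient_id,
      model = model, horizon = as.integer(horizon),
      n_used = n_used, target_index = target,
      mae = mean(abs_err),
      ms_predicted = ms_pred, ms_actual = ms[target],
      ms_ae = abs(ms_pred - ms[target])
    )
    if (keep_pointwise) {
      row$predicted <- list(predicted)
      row$actual <- list(actual)
      row$pw_abs_errors <- list(abs_err)
    }
    rows[[i]] <- row
  }
  dplyr::bind_rows(rows)
}

#' Evaluate a cohort over models and horizons
#'
#' @param cohort A list of prepared [vf_series()].
#' @param models Character vector of [model_kinds()].
#' @param horizons Integer vector within 1..3.
#' @inheritParams evaluate_eye
#' @return Stacked [evaluate_eye()] tibble.
#' @export
evaluate_cohort <- function(cohort, models = "olslr", horizons = 1:3,
                            clamp = FALSE, keep_pointwise = FALSE) {
  combos <- expand.grid(model = models, horizon = horizons,
                        stringsAsFactors = FALSE)
  out <- vector("list", length(cohort) * nrow(combos))
  k <- 0L
  for (s in cohort) {
    for (i in seq_len(nrow(combos))) {
      k <- k + 1L
      out[[k]] <- evaluate_eye(s, combos$model[i], combos$horizon[i],
                               clamp = clamp, keep_pointwise = keep_pointwise)
    }
  }
  dplyr::bind_rows(out)
}

#' Aggregate per-eye prediction errors into evaluation cells
#'
#' Groups outcomes by (model, horizon, n_used) and summarizes the chosen error
#' column across eyes: mean, SD (denominator n-1), SE and the 95% normal
#' confidence interval of the mean (`mean +- 1.96 SE`). Groups with a single
#' eye keep the mean but have `NA` spread and CI.
#'
#' @param outcomes Output of [evaluate_cohort()] / [evaluate_eye()].
#' @param value Error column to summarize: `"mae"` (point-wise path) or
#'   `"ms_ae"` (mean-sensitivity path).
#' @return A tibble of cells: `model, horizon, n_used, n_eyes, mean_mae,
#'   sd_mae, se_mae, ci_low, ci_high, analysis_path`.
#' @export
aggregate_outcomes <- function(outcomes, value = c("mae", "ms_ae")) {
  value <- match.arg(value)
  v <- rlang::sym(value)
  cells <- outcomes |>
    dplyr::group_by(.data$model, .data$horizon, .data$n_used) |>
    dplyr::summarise(
      n_eyes = dplyr::n(),
      mean_mae = mean(!!v),
      sd_mae = stats::sd(!!v),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se_mae = .data$sd_mae / sqrt(.data$n_eyes),
      ci_low = .data$mean_mae - 1.96 * .data$se_mae,
      ci_high = .data$mean_mae + 1.96 * .data$se_mae,
      analysis_path = if (value == "mae") "PW" else "MS"
    )
  cells
}

#' Number of tests required to reach the best window's confidence interval
#'
#' From the reference-model (OLSLR) cells of one horizon: the best window is
#' the one with the smallest mean error (ties broken toward the longest
#' series); its 95% CI upper bound is the saturation level; the number of
#' tests required is the smallest window length whose mean error falls at or
#' below that level. Mean error approaches its minimum from above as windows
#' lengthen, so "reaching the CI" is read as dropping below its upper bound.
#'
#' @param cells [aggregate_outcomes()] rows for a single model and horizon.
#' @return A one-row tibble: `horizon, best_n_used, best_mae, ci_upper,
#'   n_required`.
#' @export
find_saturation <- function(cells) {
  stopifnot(length(unique(cells$horizon)) == 1L,
            length(unique(cells$model)) == 1L)
  horizon <- cells$horizon[1L]
  expected <- enumerate_windows(horizon)$n_used
  missing_w <- setdiff(expected, cells$n_used)
  if (length(missing_w)) {
    stop("missing windows for horizon ", horizon, ": ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  cells <- cells[order(cells$n_used), , drop = FALSE]
  best <- which(cells$mean_mae == min(cells$mean_mae))
  best <- best[length(best)] # tie -> longest series
  ci_upper <- cells$ci_high[best]
  # absolute guard so exact-arithmetic cohorts (all means ~0 within rounding
  # error) saturate immediately; no effect at clinical error magnitudes
  reached <- which(cells$mean_mae <= ci_upper + 1e-10)
  tibble::tibble(
    horizon = as.integer(horizon),
    best_n_used = cells$n_used[best],
    best_mae = cells$mean_mae[best],
    ci_upper = ci_upper,
    n_required = cells$n_used[reached[1L]]
  )
}

#' Mean-deviation slope of a prepared series
#'
#' OLS slope (dB/year) of the mean deviation over time across all retained
#' tests; the conventional summary rate of visual-field progression.
#'
#' @param series A prepared [vf_series()].
#' @param norm A [normative_grid()].
#' @return Slope in dB/year.
#' @export
md_slope <- function(series, norm = normative_grid()) {
  md <- md_series(series, norm)
  unname(fit_olslr(series$time_years, md)$params["a"])
}

#' Severity and progression subgroup of one eye
#'
#' Severity splits at an initial MD of -20 dB (better than -20: early to
#' moderate; worse: advanced) and progression at an MD slope of -0.25 dB/year
#' (slower decline: stable; faster: progressive). Boundary values go to the
#' less severe group.
#'
#' @param series A prepared [vf_series()].
#' @param norm A [normative_grid()].
#' @return A one-row tibble: `eye_id, initial_md, md_slope, severity,
#'   progression`.
#' @export
classify_subgroups <- function(series, norm = normative_grid()) {
  md0 <- mean_deviation(series, norm, test_index = 1L)
  sl <- md_slope(series, norm)
  tibble::tibble(
    eye_id = series$eye_id,
    patient_id = series$patient_id,
    initial_md = md0,
    md_slope = sl,
    severity = if (md0 >= -20) "early_moderate" else "advanced",
    progression = if (sl >= -0.25) "stable" else "progressive"
  )
}

#' Run the full rolling-prediction experiment on a cohort
#'
#' Orchestrates the whole evaluation: per-eye rolling predictions for every
#' requested model and horizon, point-wise and mean-sensitivity aggregation
#' (overall and within severity / progression subgroups), and the saturation
#' rule applied to the reference model per horizon on both analysis paths.
#' Deterministic given the cohort and arguments.
#'
#' @param cohort A list of prepared [vf_series()].
#' @param models Models to run; the reference model `"olslr"` is always
#'   included.
#' @param horizons Horizons (subset of 1:3).
#' @param norm A [normative_grid()] for subgroup classification.
#' @param clamp Truncate predictions into `[0, 40]`?
#' @param subgroups Also aggregate within subgroups?
#' @return A list: `outcomes` (per eye-window), `subgroups` (per-eye labels),
#'   `cells` (overall and subgroup evaluation cells, both paths),
#'   `saturation` (per horizon and path, reference model).
#' @export
run_experiment <- function(cohort, models = model_kinds(), horizons = 1:3,
                           norm = normative_grid(), clamp = FALSE,
                           subgroups = TRUE) {
  models <- union("olslr", models)
  outcomes <- evaluate_cohort(cohort, models, horizons, clamp = clamp)
  labels <- dplyr::bind_rows(lapply(cohort, classify_subgroups, norm = norm))

  paths <- c("mae", "ms_ae")
  cells <- dplyr::bind_rows(lapply(paths, function(v) {
    dplyr::mutate(aggregate_outcomes(outcomes, v), subgroup = "overall")
  }))
  if (subgroups) {
    with_labels <- dplyr::left_join(
      outcomes, labels[, c("eye_id", "severity", "progression")], by = "eye_id"
    )
    for (dim in c("severity", "progression")) {
      for (lev in unique(with_labels[[dim]])) {
        sub <- with_labels[with_labels[[dim]] == lev, , drop = FALSE]
        cells <- dplyr::bind_rows(cells, dplyr::bind_rows(lapply(paths, function(v) {
          dplyr::mutate(aggregate_outcomes(sub, v), subgroup = lev)
        })))
      }
    }
  }

  saturation <- dplyr::bind_rows(lapply(horizons, function(h) {
    dplyr::bind_rows(lapply(c("PW", "MS"), function(p) {
      ref <- cells[cells$model == "olslr" & cells$horizon == h &
                     cells$analysis_path == p & cells$subgroup == "overall", ]
      dplyr::mutate(find_saturation(ref), analysis_path = p)
    }))
  }))

  list(outcomes = outcomes, subgroups = labels, cells = cells,
       saturation = saturation)
}
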