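#' Construct a visual-field series for one eye
#'
#' A `vf_series` holds the longitudinal Humphrey 10-2 examinations of a single
#' eye: a `T x 68` matrix of point-wise sensitivities (dB) with one row per
#' test in chronological order, the test times in years since the first test,
#' and per-test reliability indices.
#'
#' @param eye_id,patient_id Opaque identifiers (coerced to character).
#' @param laterality `"left"` or `"right"`.
#' @param time_years Numeric vector of test times, years since the first test;
#'   strictly increasing, first element 0.
#' @param sens Numeric matrix, one row per test, 68 columns in
#'   [build_grid_10_2()] order; values in `[0, 40]` dB.
#' @param fixation_loss_pct,false_positive_pct Per-test reliability indices in
#'   percent (`[0, 100]`).
#' @param prepared Logical; marks a series that [prepare_series()] has already
#'   filtered to exactly 13 reliable tests.
#' @return An object of class `vf_series`.
#' @export
vf_series <- function(eye_id, patient_id = eye_id, laterality = "right",
                      time_years, sens,
                      fixation_loss_pct = rep(0, length(time_years)),
                      false_positive_pct = rep(0, length(time_years)),
                      prepared = FALSE) {
  sens <- as.matrix(sens)
  n <- length(time_years)
  if (!is.numeric(time_years) || n < 1L) {
    stop("`time_years` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(diff(time_years) <= 0)) {
    stop("`time_years` must be strictly increasing", call. = FALSE)
  }
  if (abs(time_years[1L]) > 1e-9) {
    stop("first test must be at time_years = 0", call. = FALSE)
  }
  if (nrow(sens) != n || ncol(sens) != N_POINTS) {
    stop(sprintf("`sens` must be a %d x %d matrix", n, N_POINTS), call. = FALSE)
  }
  if (any(!is.finite(sens)) || any(sens < 0) || any(sens > 40)) {
    stop("sensitivities must be finite and within [0, 40] dB", call. = FALSE)
  }
  stopifnot(length(fixation_loss_pct) == n, length(false_positive_pct) == n)
  if (any(fixation_loss_pct < 0 | fixation_loss_pct > 100) ||
      any(false_positive_pct < 0 | false_positive_pct > 100)) {
    stop("reliability indices must be percentages in [0, 100]", call. = FALSE)
  }
  laterality <- match.arg(laterality, c("left", "right"))
  structure(
    list(
      eye_id = as.character(eye_id),
      patient_id = as.character(patient_id),
      laterality = laterality,
      time_years = as.numeric(time_years),
      sens = unname(sens),
      fixation_loss_pct = as.numeric(fixation_loss_pct),
      false_positive_pct = as.numeric(false_positive_pct),
      prepared = isTRUE(prepared)
    ),
    class = "vf_series"
  )
}

#' @export
print.vf_series <- function(x, ...) {
  cat(sprintf(
    "<vf_series> eye %s (patient %s, %s eye): %d tests over %.2f years%s\n",
    x$eye_id, x$patient_id, x$laterality, n_tests(x),
    max(x$time_years), if (x$prepared) " [prepared]" else ""
  ))
  invisible(x)
}

n_tests <- function(series) length(series$time_years)

#' Mean sensitivity of one examination
#'
#' The unweighted arithmetic mean of the 68 point-wise sensitivities of a
#' single test, in dB.
#'
#' @param series A [vf_series()].
#' @param test_index Which test (1-based row of the series).
#' @return Mean sensitivity in dB.
#' @export
mean_sensitivity <- function(series, test_index = 1L) {
  stopifnot(inherits(series, "vf_series"),
            test_index >= 1L, test_index <= n_tests(series))
  mean(series$sens[test_index, ])
}

#' Mean sensitivities of every test in a series
#'
#' @param series A [vf_series()].
#' @return Numeric vector, one mean sensitivity (dB) per test.
#' @export
ms_series <- function(series) {
  stopifnot(inherits(series, "vf_series"))
  rowMeans(series$sens)
}

#' Normative sensitivity grid
#'
#' Age-expected sensitivities per 10-2 location, used as the reference for the
#' mean-deviation analogue computed by [mean_deviation()]. The instrument's own
#' age-corrected normative database is proprietary; within the central 10
#' degrees the eccentricity dependence of normal sensitivity is small, so the
#' default is a flat 33 dB field. Only differences and their slopes enter the
#' analyses here, so the choice of reference level is immaterial to them.
#'
#' @param values Either a single normative level in dB applied to all 68
#'   locations, or a length-68 vector.
#' @return A numeric vector of length 68 with class `normative_grid`.
#' @export
normative_grid <- function(values = 33) {
  if (length(values) == 1L) values <- rep(as.numeric(values), N_POINTS)
  if (length(values) != N_POINTS || any(values <= 0) || any(values > 40)) {
    stop("normative values must be 68 sensitivities in (0, 40] dB", call. = FALSE)
  }
  structure(as.numeric(values), class = "normative_grid")
}

#' Mean deviation of one examination
#'
#' Unweighted mean of the per-location total deviations (measured minus
#' normative sensitivity) of a single test. This is the analogue of the
#' instrument's MD index: negative values indicate loss relative to the
#' normative field. Unlike the proprietary index it is unweighted and not
#' age-corrected, which preserves ordering and slopes -- the only properties
#' the analyses use.
#'
#' @param series A [vf_series()].
#' @param norm A [normative_grid()].
#' @param test_index Which test.
#' @return Mean deviation in dB.
#' @export
mean_deviation <- function(series, norm = normative_grid(), test_index = 1L) {
  stopifnot(inherits(series, "vf_series"), inherits(norm, "normative_grid"),
            test_index >= 1L, test_index <= n_tests(series))
  mean(series$sens[test_index, ] - unclass(norm))
}

md_series <- function(series, norm = normative_grid()) {
  rowMeans(sweep(series$sens, 2L, unclass(norm)))
}

#' Is a test reliable?
#'
#' Following the manufacturer's recommendation, a test is unreliable when it
#' has more than 20% fixation losses or more than 15% false-positive errors.
#' "More than" is strict: tests at exactly 20% / 15% are retained.
#'
#' @param fixation_loss_pct,false_positive_pct Reliability indices in percent.
#' @return Logical vector.
#' @export
is_reliable <- function(fixation_loss_pct, false_positive_pct) {
  !(fixation_loss_pct > 20 | false_positive_pct > 15)
}

#' Prepare a raw series for analysis
#'
#' Drops unreliable tests (see [is_reliable()]), keeps the first 13 remaining
#' tests in chronological order, re-indexes them 1..13 and rebases time so the
#' first retained test is at 0 years. Eyes with fewer than 13 reliable tests
#' are ineligible.
#'
#' @param raw A [vf_series()] in chronological order.
#' @param n_required Number of tests retained (default 13).
#' @return A prepared [vf_series()] with exactly `n_required` tests.
#' @export
prepare_series <- function(raw, n_required = 13L) {
  stopifnot(inherits(raw, "vf_series"))
  keep <- which(is_reliable(raw$fixation_loss_pct, raw$false_positive_pct))
  if (length(keep) < n_required) {
    stop(sprintf(
      "eye %s ineligible: %d reliable tests, %d required",
      raw$eye_id, length(keep), n_required
    ), call. = FALSE)
  }
  keep <- keep[seq_len(n_required)]
  vf_series(
    eye_id = raw$eye_id, patient_id = raw$patient_id,
    laterality = raw$laterality,
    time_years = raw$time_years[keep] - raw$time_years[keep[1L]],
    sens = raw$sens[keep, , drop = FALSE],
    fixation_loss_pct = raw$fixation_loss_pct[keep],
    false_positive_pct = raw$false_positive_pct[keep],
    prepared = TRUE
  )
}

#' Prepare every eligible eye of a cohort
#'
#' Applies [prepare_series()] to each series, dropping (and reporting)
#' ineligible eyes.
#'
#' @param cohort A list of [vf_series()].
#' @param n_required Tests retained per eye.
#' @param quiet Suppress the exclusion message.
#' @return A named list of prepared series.
#' @export
prepare_cohort <- function(cohort, n_required = 13L, quiet = FALSE) {
  out <- list()
  dropped <- character()
  for (s in cohort) {
    p <- tryCatch(prepare_series(s, n_required), error = function(e) NULL)
    if (is.null(p)) dropped <- c(dropped, s$eye_id) else out[[p$eye_id]] <- p
  }
  if (length(dropped) && !quiet) {
    message(sprintf("excluded %d ineligible eye(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out
}

# ---- long-format CSV I/O ----------------------------------------------------

series_csv_cols <- c(
  "patient_id", "eye_id", "laterality", "test_index", "time_years",
  "fixation_loss_pct", "false_positive_pct", "point_index", "x_deg", "y_deg",
  "sensitivity_db"
)

#' Convert a cohort to/from the long-format examination table
#'
#' One row per (eye, test, point). `cohort_to_long()` produces the canonical
#' long table; [write_series_csv()] / [read_series_csv()] persist it.
#'
#' @param cohort A list of [vf_series()].
#' @return A tibble with columns `patient_id, eye_id, laterality, test_index,
#'   time_years, fixation_loss_pct, false_positive_pct, point_index, x_deg,
#'   y_deg, sensitivity_db`.
#' @export
cohort_to_long <- function(cohort) {
  grid <- build_grid_10_2()
  rows <- lapply(cohort, function(s) {
    nt <- n_tests(s)
    tibble::tibble(
      patient_id = s$patient_id,
      eye_id = s$eye_id,
      laterality = s$laterality,
      test_index = rep(seq_len(nt), each = N_POINTS),
      time_years = rep(s$time_years, each = N_POINTS),
      fixation_loss_pct = rep(s$fixation_loss_pct, each = N_POINTS),
      false_positive_pct = rep(s$false_positive_pct, each = N_POINTS),
      point_index = rep(grid$point_index, times = nt),
      x_deg = rep(grid$x_deg, times = nt),
      y_deg = rep(grid$y_deg, times = nt),
      sensitivity_db = as.vector(t(s$sens))
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname cohort_to_long
#' @param path File path of the CSV (UTF-8, header, `.` decimal separator).
#' @export
write_series_csv <- function(cohort, path) {
  readr::write_csv(cohort_to_long(cohort), path)
  invisible(path)
}

#' @rdname cohort_to_long
#' @param prepared Logical passed through to [vf_series()]; set `TRUE` when
#'   the file holds an already-prepared cohort.
#' @export
read_series_csv <- function(path, prepared = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(series_csv_cols, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  key <- paste(df$eye_id, df$test_index, df$point_index)
  if (anyDuplicated(key)) {
    stop("schema error: duplicate (eye, test, point) key at row ",
         which(duplicated(key))[1L], call. = FALSE)
  }
  out <- list()
  for (eid in unique(df$eye_id)) {
    d <- df[df$eye_id == eid, , drop = FALSE]
    d <- d[order(d$test_index, d$point_index), , drop = FALSE]
    idx <- unique(d$test_index)
    counts <- table(d$test_index)
    if (any(counts != N_POINTS)) {
      bad <- names(counts)[counts != N_POINTS][1L]
      stop(sprintf(
        "schema error: eye %s test %s has %d points (68 expected)",
        eid, bad, as.integer(counts[bad])
      ), call. = FALSE)
    }
    per_test <- d[!duplicated(d$test_index), , drop = FALSE]
    out[[as.character(eid)]] <- vf_series(
      eye_id = eid,
      patient_id = per_test$patient_id[1L],
      laterality = per_test$laterality[1L],
      time_years = per_test$time_years,
      sens = matrix(d$sensitivity_db, nrow = length(idx), ncol = N_POINTS,
                    byrow = TRUE),
      fixation_loss_pct = per_test$fixation_loss_pct,
      false_positive_pct = per_test$false_positive_pct,
      prepared = prepared
    )
  }
  out
}

#' Read / write a normative grid CSV
#'
#' Columns: `point_index, x_deg, y_deg, normative_db`.
#'
#' @param path CSV file path.
#' @export
read_normative_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("point_index", "normative_db") %in% names(df))) {
    stop("schema error: normative CSV needs point_index and normative_db",
         call. = FALSE)
  }
  normative_grid(df$normative_db[order(df$point_index)])
}

#' @rdname read_normative_csv
#' @param norm A [normative_grid()].
#' @export
write_normative_csv <- function(norm, path) {
  grid <- build_grid_10_2()
  grid$normative_db <- unclass(norm)
  readr::write_csv(grid, path)
  invisible(path)
}
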