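#' Configuration of the synthetic 10-2 cohort generator
#'
#' Returns the default generator configuration, optionally overriding fields.
#' The defaults emulate a severe, slowly progressing open-angle-glaucoma
#' cohort followed with Humphrey 10-2 tests about every 6 months: 180 eyes in
#' 133 patients, 13 reliable tests per eye over about 7.5 years, initial MD
#' of -19.8 +- 8.1 dB and an MD slope of -0.33 +- 0.40 dB/year.
#'
#' @param ... Named overrides of any field below.
#' @return A `synth_config` list with fields:
#' \describe{
#'   \item{n_patients, n_eyes}{Cohort size; `n_eyes - n_patients` patients
#'     contribute both eyes (`n_eyes <= 2 n_patients`).}
#'   \item{n_tests}{Reliable tests generated per eye (13).}
#'   \item{interval_years_mean, interval_jitter_sd}{Mean and SD of the
#'     interval between consecutive reliable tests, years (0.625, 0.15).}
#'   \item{baseline_md_mean, baseline_md_sd}{Moments of the initial MD
#'     distribution, dB (-19.8, 8.1); realized as a truncated normal on
#'     `[-33, 0]` whose mean is calibrated to `baseline_md_mean`.}
#'   \item{md_slope_mean, md_slope_sd}{Eye-level MD slope distribution,
#'     dB/year (-0.33, 0.40).}
#'   \item{within_patient_slope_correlation}{Correlation of severity and slope
#'     between the two eyes of a bilateral patient (0.5).}
#'   \item{pointwise_slope_sd}{SD of the spatially correlated perturbation
#'     added to each location's slope, dB/year (0.2).}
#'   \item{defect_sd_db, defect_correlation_length_deg}{Marginal SD (7 dB) and
#'     squared-exponential correlation length (4 deg) of the baseline defect
#'     field.}
#'   \item{noise_sd_at_ceiling, noise_sd_at_floor, noise_reference_db}{
#'     Test-retest noise SD interpolated linearly in the true sensitivity:
#'     1.5 dB at 35 dB, growing to 4 dB at 0 dB.}
#'   \item{truth_shape}{Shape of the true point-wise trajectory: `"linear"`
#'     (default), `"exponential"` or `"logistic"`.}
#'   \item{unreliable_test_rate}{Probability of inserting an unreliable extra
#'     test into each inter-test gap (0.05).}
#'   \item{round_to_integer}{Round measured dB to integers, as the instrument
#'     reports (TRUE).}
#'   \item{normative_db}{Flat normative level, dB (33).}
#'   \item{seed}{Integer RNG seed.}
#' }
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_patients = 133L, n_eyes = 180L, n_tests = 13L,
    interval_years_mean = 0.625, interval_jitter_sd = 0.15,
    baseline_md_mean = -19.8, baseline_md_sd = 8.1,
    md_slope_mean = -0.33, md_slope_sd = 0.40,
    within_patient_slope_correlation = 0.5,
    pointwise_slope_sd = 0.2,
    defect_sd_db = 7, defect_correlation_length_deg = 4,
    noise_sd_at_ceiling = 1.5, noise_sd_at_floor = 4.0,
    noise_reference_db = 35,
    truth_shape = "linear",
    unreliable_test_rate = 0.05,
    round_to_integer = TRUE,
    normative_db = 33,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown synth_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (cfg$n_eyes > 2L * cfg$n_patients) {
    stop("cannot seat ", cfg$n_eyes, " eyes in ", cfg$n_patients, " patients",
         call. = FALSE)
  }
  sds <- c(cfg$interval_jitter_sd, cfg$baseline_md_sd, cfg$md_slope_sd,
           cfg$pointwise_slope_sd, cfg$defect_sd_db,
           cfg$noise_sd_at_ceiling, cfg$noise_sd_at_floor)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (cfg$interval_years_mean <= 0) stop("intervals must be positive", call. = FALSE)
  cfg$truth_shape <- match.arg(cfg$truth_shape,
                               c("linear", "exponential", "logistic"))
  structure(cfg, class = "synth_config")
}

# mean of Normal(mu, sd) truncated to [a, b]
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  z <- stats::pnorm(be) - stats::pnorm(al)
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / z
}

# quantile function of the truncated normal
truncnorm_quantile <- function(p, mu, sd, a, b) {
  pa <- stats::pnorm(a, mu, sd); pb <- stats::pnorm(b, mu, sd)
  stats::qnorm(pa + p * (pb - pa), mu, sd)
}

# proposal mean whose [a, b]-truncated distribution has the target mean
truncnorm_calibrate <- function(target, sd, a, b) {
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, a, b) - target,
                 lower = target - 3 * sd - 5, upper = target + 3 * sd + 5,
                 tol = 1e-9)$root
}

# Cholesky factor of the squared-exponential spatial correlation over the grid
grid_correlation_chol <- function(length_deg) {
  grid <- build_grid_10_2()
  d2 <- outer(grid$x_deg, grid$x_deg, "-")^2 +
    outer(grid$y_deg, grid$y_deg, "-")^2
  K <- exp(-d2 / (2 * length_deg^2))
  chol(K + diag(1e-8, N_POINTS))
}

noise_sd_at <- function(truth, cfg) {
  frac <- pmin(pmax(truth, 0), cfg$noise_reference_db) / cfg$noise_reference_db
  cfg$noise_sd_at_floor +
    (cfg$noise_sd_at_ceiling - cfg$noise_sd_at_floor) * frac
}

# true trajectory of one eye: baseline (68), per-point slope (68), times
truth_trajectory <- function(baseline, slope, times, shape) {
  n <- length(times)
  out <- matrix(0, n, N_POINTS)
  for (i in seq_len(n)) {
    t <- times[i]
    y <- switch(shape,
      linear = baseline + slope * t,
      exponential = {
        g <- ifelse(baseline > 0, slope / pmax(baseline, 1), 0)
        baseline * exp(g * t)
      },
      logistic = {
        p0 <- pmin(pmax(baseline / 40, 0.01), 0.99)
        k <- ifelse(baseline > 0, slope / (40 * p0 * (1 - p0)), 0)
        40 / (1 + exp(-(log(p0 / (1 - p0)) + k * t)))
      }
    )
    out[i, ] <- pmax(y, 0)
  }
  out
}

#' Generate a synthetic longitudinal 10-2 cohort
#'
#' Simulates raw per-eye examination series with the structure the trend
#' analyses assume, together with the generating truth for parameter-recovery
#' checks. Per patient, a severity and a progression effect are drawn so that
#' both eyes of a bilateral patient are correlated (Gaussian copula). Per eye:
#'
#' * the initial MD target comes from a normal distribution truncated to
#'   `[-33, 0]` dB and calibrated so its mean equals `baseline_md_mean`;
#' * baseline sensitivities are the flat normative field plus a spatially
#'   correlated defect field, shifted so the clamped (`[0, 35]` dB) field hits
#'   the MD target exactly;
#' * the eye's MD progression rate is spread over the locations that still
#'   have measurable sensitivity (a floored location cannot decline further),
#'   plus a spatially correlated per-location perturbation;
#' * true trajectories follow `truth_shape` and are floored at 0 dB;
#' * measurements add heteroscedastic noise (SD interpolating from
#'   `noise_sd_at_ceiling` at `noise_reference_db` down to `noise_sd_at_floor`
#'   at 0 dB), are censored into `[0, 40]` and integer-rounded;
#' * reliable tests follow the configured visit schedule; unreliable extra
#'   tests (violating the fixation-loss / false-positive thresholds) are
#'   inserted into inter-test gaps at rate `unreliable_test_rate`, so at least
#'   `n_tests` reliable tests always remain.
#'
#' @param config A [synth_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list: `cohort` (raw [vf_series()] list, unreliable tests
#'   included), `truth` (list of tibbles `eyes` and `points`), and `norm`
#'   (the [normative_grid()] used).
#' @export
generate_cohort <- function(config = synth_config(), seed = NULL) {
  cfg <- config
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(seed)) cfg$seed <- seed
  set.seed(cfg$seed)

  L <- grid_correlation_chol(cfg$defect_correlation_length_deg)
  norm <- normative_grid(cfg$normative_db)
  norm_level <- cfg$normative_db

  # seat eyes in patients: the first n_eyes - n_patients patients are bilateral
  n_bilateral <- cfg$n_eyes - cfg$n_patients
  eyes_per_patient <- c(rep(2L, n_bilateral), rep(1L, cfg$n_patients - n_bilateral))

  mu_star <- if (cfg$baseline_md_sd > 0) {
    truncnorm_calibrate(cfg$baseline_md_mean, cfg$baseline_md_sd, -33, 0)
  } else cfg$baseline_md_mean

  rho <- cfg$within_patient_slope_correlation
  cohort <- list()
  eye_rows <- list()
  point_rows <- list()

  # -- phase A: draw all randomness and the per-eye latent structure --------
  draws <- list()
  for (p in seq_len(cfg$n_patients)) {
    patient_id <- sprintf("P%03d", p)
    n_e <- eyes_per_patient[p]
    # patient-level latent severity / progression factors (Gaussian copula)
    u_sev <- stats::rnorm(1L); u_slope <- stats::rnorm(1L)
    lateralities <- if (n_e == 2L) c("right", "left") else {
      sample(c("right", "left"), 1L)
    }
    for (e in seq_len(n_e)) {
      eye_id <- sprintf("%s_%s", patient_id, substr(lateralities[e], 1, 1))
      z_sev <- sqrt(rho) * u_sev + sqrt(1 - rho) * stats::rnorm(1L)
      z_slope <- sqrt(rho) * u_slope + sqrt(1 - rho) * stats::rnorm(1L)

      md_target <- if (cfg$baseline_md_sd > 0) {
        truncnorm_quantile(stats::pnorm(z_sev), mu_star, cfg$baseline_md_sd,
                           -33, 0)
      } else cfg$baseline_md_mean
      m_drawn <- cfg$md_slope_mean + cfg$md_slope_sd * z_slope

      # baseline field: normative + correlated defect, shifted to hit md_target
      defect <- cfg$defect_sd_db * drop(crossprod(L, stats::rnorm(N_POINTS)))
      f <- function(shift) {
        mean(pmin(pmax(norm_level + shift + defect, 0), 35)) -
          (norm_level + md_target)
      }
      shift <- stats::uniroot(f, lower = -250, upper = 60, tol = 1e-9)$root
      baseline <- pmin(pmax(norm_level + shift + defect, 0), 35)
      pert <- cfg$pointwise_slope_sd * drop(crossprod(L, stats::rnorm(N_POINTS)))

      # visit schedule: reliable tests first, unreliable inserted into gaps
      gaps <- if (cfg$n_tests > 1L) {
        pmax(stats::rnorm(cfg$n_tests - 1L, cfg$interval_years_mean,
                          cfg$interval_jitter_sd), 0.1)
      } else numeric(0)
      t_rel <- cumsum(c(0, gaps))
      times <- t_rel
      reliable <- rep(TRUE, cfg$n_tests)
      if (cfg$unreliable_test_rate > 0 && cfg$n_tests > 1L) {
        ins <- which(stats::runif(cfg$n_tests - 1L) < cfg$unreliable_test_rate)
        if (length(ins)) {
          t_ins <- t_rel[ins] + stats::runif(length(ins), 0.2, 0.8) * gaps[ins]
          times <- c(times, t_ins)
          reliable <- c(reliable, rep(FALSE, length(ins)))
          ord <- order(times)
          times <- times[ord]; reliable <- reliable[ord]
        }
      }
      n_v <- length(times)
      noise_z <- matrix(stats::rnorm(n_v * N_POINTS), n_v, N_POINTS)
      fl <- fp <- numeric(n_v)
      for (i in seq_len(n_v)) {
        if (reliable[i]) {
          fl[i] <- stats::runif(1L, 0, 20)
          fp[i] <- stats::runif(1L, 0, 15)
        } else if (stats::runif(1L) < 0.5) {
          fl[i] <- stats::runif(1L, 21, 60)
          fp[i] <- stats::runif(1L, 0, 15)
        } else {
          fl[i] <- stats::runif(1L, 0, 20)
          fp[i] <- stats::runif(1L, 16, 40)
        }
      }

      draws[[eye_id]] <- list(
        eye_id = eye_id, patient_id = patient_id,
        laterality = lateralities[e],
        md_target = md_target, m_drawn = m_drawn,
        baseline = baseline, pert = pert,
        t_rel = t_rel, times = times, reliable = reliable,
        noise_z = noise_z, fl = fl, fp = fp
      )
    }
  }

  # Per-point slopes are theta * reserve + pert on the locations above the
  # floor, where reserve is sensitivity relative to the island mean: decline
  # sits on locations that still have sensitivity to lose. md_curve(theta) is
  # the OLS slope of the floored true MD trajectory over the eye's schedule;
  # theta is solved so that slope equals the eye's target rate. md_curve is
  # not monotone for declining eyes (once the whole island floors before
  # follow-up ends, steeper decline flattens the fitted slope again), so the
  # root is sought on the branch before the deepest achievable decline and
  # capped there when the target is beyond what the eye can express.
  eye_slope_machinery <- function(d) {
    active <- d$baseline > 0
    if (!any(active) || cfg$n_tests < 2L) return(NULL)
    tc <- d$t_rel - mean(d$t_rel)
    w_ols <- tc / sum(tc^2)
    reserve <- d$baseline / mean(d$baseline[active])
    md_curve <- function(theta) {
      s <- numeric(N_POINTS)
      s[active] <- theta * reserve[active] + d$pert[active]
      traj <- truth_trajectory(d$baseline, s, d$t_rel, cfg$truth_shape)
      mean(drop(w_ols %*% traj))
    }
    theta_peak <- stats::optimize(md_curve, c(-25, 0), tol = 1e-6)$minimum
    list(active = active, reserve = reserve, md_curve = md_curve,
         p0 = md_curve(0), peak = md_curve(theta_peak),
         theta_peak = theta_peak)
  }
  machinery <- lapply(draws, eye_slope_machinery)

  # Achievable MD slope of one eye given a target rate: the target itself
  # where expressible, otherwise the nearest expressible value.
  achieved_slope <- function(mach, m) {
    if (is.null(mach)) return(0)
    if (m > mach$p0) m else max(m, mach$peak)
  }

  # -- cohort-level calibration: shift the latent progression distribution so
  # the expressible cohort mean equals the configured mean (the configured
  # moments describe the realized, measurable cohort) ------------------------
  delta <- 0
  if (cfg$n_tests > 1L && length(draws)) {
    m_drawn_all <- vapply(draws, `[[`, numeric(1), "m_drawn")
    mean_ach <- function(dd) {
      mean(mapply(function(mach, m) achieved_slope(mach, m + dd),
                  machinery, m_drawn_all))
    }
    gd <- function(dd) mean_ach(dd) - cfg$md_slope_mean
    if (abs(gd(0)) > 1e-10) {
      lo <- -2; hi <- 2
      if (gd(lo) * gd(hi) < 0) {
        delta <- stats::uniroot(gd, c(lo, hi), tol = 1e-8)$root
      } else {
        delta <- if (abs(gd(lo)) < abs(gd(hi))) lo else hi
        warning("slope calibration hit its bound; configured progression ",
                "rate may not be expressible by this cohort", call. = FALSE)
      }
    }
  }

  # -- phase B: build trajectories, measurements and records (no RNG) --------
  for (eye_id in names(draws)) {
    d <- draws[[eye_id]]
    mach <- machinery[[eye_id]]
    slopes <- numeric(N_POINTS)
    true_md_slope <- 0
    if (!is.null(mach)) {
      m_t <- d$m_drawn + delta
      theta <- if (m_t > mach$p0) {
        hi <- 1
        while (mach$md_curve(hi) < m_t && hi < 128) hi <- hi * 2
        if (mach$md_curve(hi) < m_t) hi
        else stats::uniroot(function(th) mach$md_curve(th) - m_t, c(0, hi),
                            tol = 1e-8)$root
      } else if (m_t <= mach$peak) {
        mach$theta_peak
      } else {
        stats::uniroot(function(th) mach$md_curve(th) - m_t,
                       c(mach$theta_peak, 0), tol = 1e-8)$root
      }
      slopes[mach$active] <- theta * mach$reserve[mach$active] +
        d$pert[mach$active]
      true_md_slope <- mach$md_curve(theta)
    }

    truth <- truth_trajectory(d$baseline, slopes, d$times, cfg$truth_shape)
    meas <- truth + d$noise_z * noise_sd_at(truth, cfg)
    meas <- pmin(pmax(meas, 0), 40)
    if (cfg$round_to_integer) meas <- round(meas)

    cohort[[eye_id]] <- vf_series(
      eye_id = eye_id, patient_id = d$patient_id, laterality = d$laterality,
      time_years = d$times, sens = meas,
      fixation_loss_pct = d$fl, false_positive_pct = d$fp
    )
    eye_rows[[eye_id]] <- tibble::tibble(
      eye_id = eye_id, patient_id = d$patient_id, laterality = d$laterality,
      true_initial_md = d$md_target,
      eye_slope_drawn = d$m_drawn,
      eye_slope_target = d$m_drawn + delta,
      true_md_slope = true_md_slope,
      severity_true = if (d$md_target >= -20) "early_moderate" else "advanced",
      progression_true = if (true_md_slope >= -0.25) "stable" else "progressive"
    )
    point_rows[[eye_id]] <- tibble::tibble(
      eye_id = eye_id, point_index = seq_len(N_POINTS),
      true_baseline_db = d$baseline,
      true_slope_db_per_year = slopes
    )
  }

  list(
    cohort = cohort,
    truth = list(eyes = dplyr::bind_rows(eye_rows),
                 points = dplyr::bind_rows(point_rows)),
    norm = norm
  )
}

#' Deterministic single-eye fixtures
#'
#' Small analytic series for unit tests and worked examples.
#'
#' * `"noise_free_linear"`: every location declines exactly linearly
#'   (`baseline + slope * t`, floored at 0).
#' * `"constant"`: every test identical at `level` dB.
#' * `"outlier_series"`: a linear trend with one test shifted by `offset` dB.
#' * `"nonlinear_truth"`: exponential decay `baseline * exp(rate * t)`.
#'
#' @param kind Fixture kind.
#' @param slope,baseline Per-point slope (dB/year) and baseline (dB); scalars
#'   are recycled over the 68 locations.
#' @param level Constant level, dB.
#' @param offset,at_test Outlier shift (dB) and the 1-based test it hits.
#' @param rate Exponential decay rate (1/year).
#' @param n_tests,interval_years Schedule (13 tests, 0.625 years apart).
#' @param eye_id,patient_id Identifiers.
#' @return A prepared [vf_series()].
#' @export
make_fixture <- function(kind = c("noise_free_linear", "constant",
                                  "outlier_series", "nonlinear_truth"),
                         slope = -1, baseline = 30, level = 25,
                         offset = -15, at_test = 5L, rate = -0.05,
                         n_tests = 13L, interval_years = 0.625,
                         eye_id = "fixture", patient_id = eye_id) {
  kind <- match.arg(kind)
  times <- seq(0, by = interval_years, length.out = n_tests)
  slope <- rep_len(slope, N_POINTS)
  baseline <- rep_len(baseline, N_POINTS)
  sens <- switch(kind,
    noise_free_linear = t(vapply(times, function(t) pmax(baseline + slope * t, 0),
                                 numeric(N_POINTS))),
    constant = matrix(level, n_tests, N_POINTS),
    outlier_series = {
      m <- t(vapply(times, function(t) pmax(baseline + slope * t, 0),
                    numeric(N_POINTS)))
      m[at_test, ] <- pmin(pmax(m[at_test, ] + offset, 0), 40)
      m
    },
    nonlinear_truth = t(vapply(times, function(t) baseline * exp(rate * t),
                               numeric(N_POINTS)))
  )
  vf_series(eye_id = eye_id, patient_id = patient_id,
            time_years = times, sens = sens, prepared = TRUE)
}

#' Write a generated cohort and its truth record to disk
#'
#' @param generated Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `cohort.csv` (long examination table),
#'   `truth_eye.csv`, `truth.csv` and `normative.csv`.
#' @export
write_cohort <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series_csv(generated$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(generated$truth$eyes, file.path(dir, "truth_eye.csv"))
  readr::write_csv(generated$truth$points, file.path(dir, "truth.csv"))
  write_normative_csv(generated$norm, file.path(dir, "normative.csv"))
  invisible(dir)
}
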