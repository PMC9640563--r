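#' Trend models for point-wise visual-field sensitivity
#'
#' Five per-location trend models are supported, each regressing sensitivity
#' (dB) on time (years since the first test):
#'
#' * `"olslr"` -- ordinary least-squares linear regression, `y = a x + b`;
#' * `"exponential"` -- `y = exp(a x + b)`, fitted by nonlinear least squares
#'   in dB space;
#' * `"quadratic"` -- `y = a x^2 + b x + c`, polynomial least squares;
#' * `"m_robust"` -- straight line fitted by Huber M-estimation (iteratively
#'   reweighted least squares);
#' * `"logistic"` -- `y/40 = 1 / (1 + exp(a x + b))`, nonlinear least squares
#'   on the 0-1 scale with predictions rescaled by 40.
#'
#' @name vf_models
#' @return `model_kinds()` returns the five model names.
NULL

#' @rdname vf_models
#' @export
model_kinds <- function() {
  c("olslr", "exponential", "quadratic", "m_robust", "logistic")
}

new_vf_fit <- function(model, params, n_obs, converged = TRUE, scale = NA_real_) {
  structure(
    list(model = model, params = params, scale = scale,
         converged = converged, n_obs = n_obs),
    class = "vf_fit"
  )
}

#' @export
print.vf_fit <- function(x, ...) {
  cat(sprintf("<vf_fit:%s> %s (n = %d%s)\n", x$model,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$n_obs, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

check_xy <- function(x, y, min_n = 2L) {
  stopifnot(length(x) == length(y))
  if (length(x) < min_n) {
    stop(sprintf("need at least %d observations", min_n), call. = FALSE)
  }
  if (diff(range(x)) < .Machine$double.eps) {
    stop("singular design: all time values are equal", call. = FALSE)
  }
  invisible(NULL)
}

#' Ordinary least-squares straight-line fit
#'
#' Closed-form normal-equation solution of `y = a x + b`.
#'
#' @param x Times in years.
#' @param y Sensitivities in dB.
#' @return A `vf_fit` with params `(a, b)` (slope dB/year, intercept dB).
#' @export
fit_olslr <- function(x, y) {
  check_xy(x, y)
  xb <- mean(x); yb <- mean(y)
  a <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  new_vf_fit("olslr", c(a = a, b = yb - a * xb), n_obs = length(x))
}

#' Quadratic least-squares fit
#'
#' `y = a x^2 + b x + c` by polynomial least squares; requires at least three
#' distinct time values.
#'
#' @inheritParams fit_olslr
#' @return A `vf_fit` with params `(a, b, c)`.
#' @export
fit_quadratic <- function(x, y) {
  check_xy(x, y, min_n = 3L)
  if (length(unique(x)) < 3L) {
    stop("singular design: need >= 3 distinct time values", call. = FALSE)
  }
  X <- cbind(x^2, x, 1)
  beta <- unname(qr.solve(X, y))
  new_vf_fit("quadratic", c(a = beta[1L], b = beta[2L], c = beta[3L]),
             n_obs = length(x))
}

#' Exponential trend fit
#'
#' `y = exp(a x + b)`, fitted by least squares in the observation (dB) space
#' with Levenberg-Marquardt iterations, initialized from a straight-line fit
#' of `log(pmax(y, 0.1))` on `x`. If the optimizer fails, the initializer fit
#' is returned with `converged = FALSE`.
#'
#' @inheritParams fit_olslr
#' @return A `vf_fit` with params `(a, b)`.
#' @export
fit_exponential <- function(x, y) {
  check_xy(x, y)
  if (all(y <= 0)) stop("degenerate data: all sensitivities are 0", call. = FALSE)
  init <- fit_olslr(x, log(pmax(y, 0.1)))
  start <- list(a = unname(init$params["a"]), b = unname(init$params["b"]))
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ exp(a * x + b), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_vf_fit("exponential", c(a = start$a, b = start$b),
                      n_obs = length(x), converged = FALSE))
  }
  cf <- stats::coef(fit)
  new_vf_fit("exponential", c(a = unname(cf["a"]), b = unname(cf["b"])),
             n_obs = length(x))
}

#' Logistic trend fit
#'
#' Sensitivities are divided by 40 to map the instrument range onto (0, 1) and
#' `y/40 = 1 / (1 + exp(a x + b))` is fitted by least squares on that scale.
#' Initialization regresses `-logit` of the scaled values (clamped to
#' `[0.01, 0.99]` so the logit is finite at 0 and 40 dB) on time; the
#' objective itself uses the unclamped values. Predictions are rescaled by 40.
#'
#' @inheritParams fit_olslr
#' @return A `vf_fit` with params `(a, b)`.
#' @export
fit_logistic <- function(x, y) {
  check_xy(x, y)
  ys <- y / 40
  yc <- pmin(pmax(ys, 0.01), 0.99)
  # logit(p) = -(a x + b)  =>  regress -logit(p) on x
  init <- fit_olslr(x, -log(yc / (1 - yc)))
  start <- list(a = unname(init$params["a"]), b = unname(init$params["b"]))
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      ys ~ 1 / (1 + exp(a * x + b)), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_vf_fit("logistic", c(a = start$a, b = start$b),
                      n_obs = length(x), converged = FALSE))
  }
  cf <- stats::coef(fit)
  new_vf_fit("logistic", c(a = unname(cf["a"]), b = unname(cf["b"])),
             n_obs = length(x))
}

#' Huber M-estimator robust straight-line fit
#'
#' Minimizes the Huber objective `sum(rho(r_i))` for residuals of `y = a x + b`
#' by iteratively reweighted least squares: starting from the OLS solution,
#' each iteration re-estimates the residual scale `sigma = MAD(r) / 0.6745`
#' (MAD about zero) and applies weights `w_i = min(1, k sigma / |r_i|)` with
#' tuning constant `k = 1.345` (95% Gaussian efficiency). Iteration stops when
#' the largest coefficient change falls below `1e-8` or after 100 iterations.
#' If the scale collapses (e.g. at least half the residuals are exactly zero),
#' the OLS fit is returned unchanged.
#'
#' @inheritParams fit_olslr
#' @param k Huber tuning constant.
#' @return A `vf_fit` with params `(a, b)` and the final `scale` estimate.
#' @export
fit_m_robust <- function(x, y, k = 1.345) {
  check_xy(x, y)
  ols <- fit_olslr(x, y)
  beta <- ols$params
  X <- cbind(x, 1)
  converged <- FALSE
  sigma <- NA_real_
  for (it in seq_len(100L)) {
    r <- y - (beta["a"] * x + beta["b"])
    sigma <- stats::mad(r, center = 0)
    if (sigma < 1e-6) {
      return(new_vf_fit("m_robust", ols$params, n_obs = length(x),
                        scale = sigma))
    }
    w <- pmin(1, k * sigma / abs(r))
    w[!is.finite(w)] <- 1 # zero residual -> full weight
    sw <- sqrt(w)
    beta_new <- qr.solve(X * sw, y * sw)
    names(beta_new) <- c("a", "b")
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  new_vf_fit("m_robust", beta, n_obs = length(x), converged = converged,
             scale = sigma)
}

#' Huber objective value of a straight-line fit
#'
#' `sum(rho(r_i))` with the Huber penalty (`r^2/2` within `k * sigma`, linear
#' beyond). Useful for verifying that the robust fit improves on OLS.
#'
#' @param x,y Data.
#' @param a,b Line coefficients.
#' @param sigma Residual scale; defaults to `MAD/0.6745` of the residuals.
#' @param k Huber tuning constant.
#' @export
huber_objective <- function(x, y, a, b, sigma = NULL, k = 1.345) {
  r <- y - (a * x + b)
  if (is.null(sigma)) sigma <- stats::mad(r, center = 0)
  thr <- k * sigma
  sum(ifelse(abs(r) <= thr, r^2 / 2, thr * abs(r) - thr^2 / 2))
}

#' Fit one model to one location's series
#'
#' @param x,y Data.
#' @param model One of [model_kinds()].
#' @return A `vf_fit`.
#' @export
fit_model <- function(x, y, model = model_kinds()) {
  model <- match.arg(model)
  switch(model,
    olslr = fit_olslr(x, y),
    exponential = fit_exponential(x, y),
    quadratic = fit_quadratic(x, y),
    m_robust = fit_m_robust(x, y),
    logistic = fit_logistic(x, y)
  )
}

#' Evaluate a fitted trend model at new times
#'
#' Evaluates the fitted formula at `x_new`; logistic output is rescaled by 40.
#' With `clamp = TRUE` predictions are truncated into the instrument range
#' `[0, 40]` dB (off by default so that model differences are preserved).
#'
#' @param object A `vf_fit`.
#' @param x_new Times (years) at which to predict.
#' @param clamp Truncate predictions into `[0, 40]`?
#' @param ... Unused.
#' @return Predicted sensitivities in dB.
#' @export
predict.vf_fit <- function(object, x_new, clamp = FALSE, ...) {
  p <- object$params
  out <- switch(object$model,
    olslr = ,
    m_robust = p["a"] * x_new + p["b"],
    exponential = exp(p["a"] * x_new + p["b"]),
    quadratic = p["a"] * x_new^2 + p["b"] * x_new + p["c"],
    logistic = 40 / (1 + exp(p["a"] * x_new + p["b"]))
  )
  out <- unname(out)
  if (clamp) out <- pmin(pmax(out, 0), 40)
  out
}

# ---- point-wise application -------------------------------------------------

#' Fit a trend model at every grid location of one eye
#'
#' Fits the chosen model independently at each of the 68 locations, using the
#' first `n_used` tests of a prepared series (x = test times, y = that
#' location's sensitivities). OLS and quadratic fits share one design-matrix
#' decomposition across locations; the nonlinear and robust models are fitted
#' per location.
#'
#' @param series A prepared [vf_series()].
#' @param n_used Number of leading tests in the fitting window (5..12).
#' @param model One of [model_kinds()].
#' @return A `pointwise_fit`: coefficient matrix `params` (68 rows), logical
#'   `converged` per location, plus `eye_id`, `model`, `n_used` and the window
#'   times.
#' @export
fit_pointwise <- function(series, n_used, model = model_kinds()) {
  model <- match.arg(model)
  stopifnot(inherits(series, "vf_series"))
  if (n_used < 2L || n_used > n_tests(series)) {
    stop("`n_used` out of range for this series", call. = FALSE)
  }
  x <- series$time_years[seq_len(n_used)]
  Y <- series$sens[seq_len(n_used), , drop = FALSE]
  converged <- rep(TRUE, N_POINTS)
  scale <- rep(NA_real_, N_POINTS)

  if (model == "olslr") {
    X <- cbind(a = x, b = 1)
    params <- t(qr.coef(qr(X), Y)) # 68 x 2
  } else if (model == "quadratic") {
    if (length(unique(x)) < 3L) {
      stop("singular design: need >= 3 distinct time values", call. = FALSE)
    }
    X <- cbind(a = x^2, b = x, c = 1)
    params <- t(qr.coef(qr(X), Y))
  } else {
    params <- matrix(NA_real_, N_POINTS, 2L,
                     dimnames = list(NULL, c("a", "b")))
    for (j in seq_len(N_POINTS)) {
      f <- tryCatch(fit_model(x, Y[, j], model), error = function(e) {
        stop(sprintf("location %d: %s", j, conditionMessage(e)), call. = FALSE)
      })
      params[j, ] <- f$params
      converged[j] <- f$converged
      scale[j] <- f$scale
    }
  }
  structure(
    list(eye_id = series$eye_id, model = model, n_used = n_used,
         x = x, params = params, converged = converged, scale = scale),
    class = "pointwise_fit"
  )
}

#' Extract one location's fit from a point-wise fit
#'
#' @param pwfit A `pointwise_fit`.
#' @param point_index Location (1..68).
#' @return A `vf_fit` for that location.
#' @export
pointwise_fit_at <- function(pwfit, point_index) {
  stopifnot(inherits(pwfit, "pointwise_fit"),
            point_index >= 1L, point_index <= N_POINTS)
  p <- pwfit$params[point_index, ]
  names(p) <- colnames(pwfit$params)
  new_vf_fit(pwfit$model, p, n_obs = pwfit$n_used,
             converged = pwfit$converged[point_index],
             scale = pwfit$scale[point_index])
}

#' Predict all 68 locations from a point-wise fit
#'
#' @param object A `pointwise_fit`.
#' @param x_new A single time (years).
#' @param clamp Truncate into `[0, 40]`?
#' @param ... Unused.
#' @return Numeric vector of 68 predicted sensitivities (dB).
#' @export
predict.pointwise_fit <- function(object, x_new, clamp = FALSE, ...) {
  stopifnot(length(x_new) == 1L)
  P <- object$params
  out <- switch(object$model,
    olslr = ,
    m_robust = P[, 1L] * x_new + P[, 2L],
    exponential = exp(P[, 1L] * x_new + P[, 2L]),
    quadratic = P[, 1L] * x_new^2 + P[, 2L] * x_new + P[, 3L],
    logistic = 40 / (1 + exp(P[, 1L] * x_new + P[, 2L]))
  )
  out <- unname(out)
  if (clamp) out <- pmin(pmax(out, 0), 40)
  out
}
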