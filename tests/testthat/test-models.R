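test_that("OLS line fitting is exact on lines and matches the normal-equation oracle", {
  f <- fit_olslr(c(0, 1, 2), c(30, 29, 28))
  expect_equal(unname(f$params), c(-1, 30))
  f2 <- fit_olslr(c(0, 1), c(5, 5))
  expect_equal(unname(f2$params), c(0, 5))
  expect_error(fit_olslr(c(2, 2, 2), c(1, 2, 3)), "singular")

  set.seed(11)
  for (i in 1:200) {
    d <- random_xy(5)
    ours <- fit_olslr(d$x, d$y)$params
    oracle <- normal_eq_fit(cbind(d$x, 1), d$y)
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-10)
  }
})

test_that("quadratic fitting interpolates three points and matches its oracle", {
  x <- c(0, 1, 2, 3)
  f <- fit_quadratic(x, x^2 - 2 * x + 1)
  expect_equal(unname(f$params), c(1, -2, 1), tolerance = 1e-10)

  # three points: saturated fit, zero residual
  x3 <- c(0, 1, 2); y3 <- c(5, 1, 9)
  f3 <- fit_quadratic(x3, y3)
  expect_equal(predict(f3, x3), y3, tolerance = 1e-9)

  expect_error(fit_quadratic(c(0, 0, 1), c(1, 2, 3)), "singular")

  set.seed(12)
  for (i in 1:200) {
    d <- random_xy(6)
    ours <- fit_quadratic(d$x, d$y)$params
    oracle <- normal_eq_fit(cbind(d$x^2, d$x, 1), d$y)
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-8)
  }
})

test_that("exponential fitting recovers its generating curve and beats its initializer", {
  x <- 0:4
  f <- fit_exponential(x, exp(-0.1 * x + 3))
  expect_equal(unname(f$params), c(-0.1, 3), tolerance = 1e-6)

  fc <- fit_exponential(x, rep(exp(2), 5))
  expect_equal(unname(fc$params), c(0, 2), tolerance = 1e-6)

  expect_error(fit_exponential(x, rep(0, 5)), "degenerate")

  set.seed(13)
  for (i in 1:25) {
    x <- sort(runif(8, 0, 7))
    y <- pmax(exp(-0.2 * x + 3) + rnorm(8, 0, 2), 0)
    f <- fit_exponential(x, y)
    init <- fit_olslr(x, log(pmax(y, 0.1)))
    sse <- function(p) sum((exp(p[1] * x + p[2]) - y)^2)
    expect_lte(sse(f$params), sse(init$params) + 1e-9)
  }
})

test_that("logistic fitting recovers its generating curve on the 0-40 scale", {
  x <- 0:6
  y <- 40 / (1 + exp(0.5 * x - 2))
  f <- fit_logistic(x, y)
  expect_equal(unname(f$params), c(0.5, -2), tolerance = 1e-4)

  # constant 20 dB is the curve's midpoint: a = 0, b = 0, prediction 20
  fc <- fit_logistic(0:4, rep(20, 5))
  expect_equal(unname(fc$params), c(0, 0), tolerance = 1e-6)
  expect_equal(predict(fc, 10), 20, tolerance = 1e-6)

  set.seed(14)
  for (i in 1:25) {
    x <- sort(runif(8, 0, 7))
    y <- pmin(pmax(40 / (1 + exp(0.4 * x - 1)) + rnorm(8, 0, 2), 0), 40)
    f <- fit_logistic(x, y)
    init_q <- -log(pmin(pmax(y / 40, 0.01), 0.99) /
                     (1 - pmin(pmax(y / 40, 0.01), 0.99)))
    init <- fit_olslr(x, init_q)
    sse <- function(p) sum((1 / (1 + exp(p[1] * x + p[2])) - y / 40)^2)
    expect_lte(sse(f$params), sse(init$params) + 1e-9)
  }
})

test_that("robust fitting equals OLS on exact lines and resists gross outliers", {
  x <- 0:4
  exact <- fit_m_robust(x, -2 * x + 30)
  expect_equal(exact$params, fit_olslr(x, -2 * x + 30)$params)

  # gross outlier: robust slope strictly closer to the generating -1 than OLS
  y <- c(30, 29, 28, 27, 6)
  rob <- fit_m_robust(x, y)
  ols <- fit_olslr(x, y)
  expect_lt(abs(rob$params["a"] - (-1)), abs(ols$params["a"] - (-1)))
  # and its Huber objective does not exceed the OLS solution's
  sig <- rob$scale
  expect_lte(
    huber_objective(x, y, rob$params["a"], rob$params["b"], sigma = sig),
    huber_objective(x, y, ols$params["a"], ols$params["b"], sigma = sig) + 1e-9
  )

  # small symmetric noise: all residuals inside the Huber threshold -> OLS
  set.seed(15)
  for (i in 1:20) {
    x <- sort(runif(10, 0, 7))
    y <- -0.5 * x + 25 + runif(10, -0.5, 0.5)
    rob <- fit_m_robust(x, y)
    ols <- fit_olslr(x, y)
    r <- y - (ols$params["a"] * x + ols$params["b"])
    if (all(abs(r) <= 1.345 * mad(r, center = 0))) {
      expect_equal(rob$params, ols$params, tolerance = 1e-6)
    }
  }
})

test_that("robust fitting agrees with the reference M-estimation implementation", {
  skip_if_not_installed("MASS")
  set.seed(16)
  for (i in 1:10) {
    x <- sort(runif(13, 0, 7.5))
    y <- pmin(pmax(-0.8 * x + 28 + rnorm(13, 0, 1.5), 0), 40)
    y[4] <- y[4] - 12
    ours <- fit_m_robust(x, y)
    ref <- MASS::rlm(y ~ x, k = 1.345, maxit = 500, acc = 1e-10)
    if (ref$converged && ours$converged) {
      expect_equal(unname(ours$params["a"]), unname(coef(ref)["x"]),
                   tolerance = 5e-3)
    }
  }
})

test_that("predictions follow the fitted formulas, with optional clamping", {
  f <- fit_olslr(c(0, 1), c(30, 29))
  expect_equal(predict(f, 3), 27)
  steep <- fit_olslr(c(0, 1), c(5, -5))
  expect_equal(predict(steep, 2, clamp = TRUE), 0)
  expect_lt(predict(steep, 2), 0)

  # exponential and logistic are bounded without clamping
  set.seed(17)
  for (i in 1:20) {
    d <- random_xy(6)
    fe <- fit_exponential(d$x, pmax(d$y, 0.5))
    fl <- fit_logistic(d$x, d$y)
    xs <- seq(-5, 25, by = 2.5)
    expect_true(all(predict(fe, xs) >= 0))
    expect_true(all(predict(fl, xs) >= 0 & predict(fl, xs) <= 40))
  }
})

test_that("point-wise fitting reproduces per-location fits and exact slopes", {
  set.seed(18)
  slopes <- runif(68, -1, -0.1)
  baselines <- runif(68, 15, 34)
  s <- make_fixture("noise_free_linear", slope = slopes, baseline = baselines)
  pw <- fit_pointwise(s, 5L, "olslr")
  expect_equal(unname(pw$params[, 1]), slopes, tolerance = 1e-9)
  expect_equal(unname(pw$params[, 2]), baselines, tolerance = 1e-9)

  # location 7 equals a manual fit on the extracted series
  noisy <- s
  noisy$sens <- pmin(pmax(s$sens + matrix(rnorm(13 * 68), 13, 68), 0), 40)
  for (model in model_kinds()) {
    pw <- fit_pointwise(noisy, 7L, model)
    manual <- fit_model(noisy$time_years[1:7], noisy$sens[1:7, 7], model)
    expect_equal(pointwise_fit_at(pw, 7L)$params, manual$params,
                 tolerance = 1e-9)
  }

  # constant eye: every model predicts the constant at any future time
  const <- make_fixture("constant", level = 20)
  for (model in model_kinds()) {
    pw <- fit_pointwise(const, 5L, model)
    expect_equal(predict(pw, 6.0), rep(20, 68), tolerance = 1e-6)
  }
})

test_that("fitters are deterministic given identical inputs", {
  set.seed(19)
  d <- random_xy(9)
  for (model in model_kinds()) {
    f1 <- fit_model(d$x, d$y, model)
    f2 <- fit_model(d$x, d$y, model)
    expect_identical(f1$params, f2$params)
  }
})
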