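test_that("window enumeration matches the three-horizon scheme", {
  w1 <- enumerate_windows(1)
  expect_equal(nrow(w1), 8L)
  expect_equal(w1$n_used, 5:12)
  expect_equal(w1$target_index, 6:13)

  w2 <- enumerate_windows(2)
  expect_equal(nrow(w2), 7L)
  expect_equal(w2$n_used[7], 11L)
  expect_equal(w2$target_index[7], 13L)

  w3 <- enumerate_windows(3)
  expect_equal(nrow(w3), 6L)
  expect_equal(w3$target_index, 8:13)

  expect_error(enumerate_windows(4), "horizon")
})

test_that("noise-free linear eyes are predicted with zero error at every window", {
  s <- linear_cohort(1)[[1]]
  for (h in 1:3) {
    ev <- evaluate_eye(s, "olslr", h)
    expect_equal(nrow(ev), c(8L, 7L, 6L)[h])
    expect_true(all(ev$mae < 1e-9))
    expect_true(all(ev$ms_ae < 1e-9))
    expect_equal(ev$target_index, ev$n_used + h)
  }
})

test_that("a uniform 2 dB prediction offset yields an MAE of exactly 2", {
  s <- linear_cohort(1)[[1]]
  # shifting every test would let the fits track the shift, so shift only the
  # predictions relative to the targets
  ev0 <- evaluate_eye(s, "olslr", 1, keep_pointwise = TRUE)
  constructed_mae <- vapply(seq_len(nrow(ev0)), function(i) {
    mean(abs((ev0$predicted[[i]] + 2) - ev0$actual[[i]]))
  }, numeric(1))
  expect_equal(constructed_mae, rep(2, nrow(ev0)), tolerance = 1e-9)
})

test_that("per-window MAE equals the brute-force mean of 68 absolute errors", {
  gen <- generate_cohort(synth_config(n_patients = 1L, n_eyes = 1L), seed = 9)
  s <- prepare_cohort(gen$cohort, quiet = TRUE)[[1]]
  ev <- evaluate_eye(s, "quadratic", 2, keep_pointwise = TRUE)
  for (i in seq_len(nrow(ev))) {
    acc <- 0
    for (j in 1:68) acc <- acc + abs(ev$predicted[[i]][j] - ev$actual[[i]][j])
    expect_equal(ev$mae[i], acc / 68, tolerance = 1e-12)
    expect_equal(ev$pw_abs_errors[[i]],
                 abs(ev$predicted[[i]] - ev$actual[[i]]))
  }
})

test_that("aggregation reproduces small-sample summaries and flags singletons", {
  oc <- tibble::tibble(
    eye_id = c("a", "b", "c"), model = "olslr", horizon = 1L, n_used = 5L,
    mae = c(1, 2, 3), ms_ae = c(1, 2, 3)
  )
  cell <- aggregate_outcomes(oc)
  expect_equal(cell$mean_mae, 2)
  expect_equal(cell$sd_mae, 1)
  expect_equal(cell$ci_low, 2 - 1.96 / sqrt(3))
  expect_equal(cell$ci_high, 2 + 1.96 / sqrt(3))

  single <- aggregate_outcomes(oc[1, ])
  expect_equal(single$mean_mae, 1)
  expect_true(is.na(single$sd_mae) && is.na(single$ci_high))

  set.seed(21)
  big <- tibble::tibble(
    eye_id = sprintf("e%03d", 1:100), model = "olslr", horizon = 1L,
    n_used = 8L, mae = runif(100, 1, 4), ms_ae = runif(100, 0, 2)
  )
  cell <- aggregate_outcomes(big, "ms_ae")
  expect_equal(cell$mean_mae, sum(big$ms_ae) / 100, tolerance = 1e-12)
  expect_equal(cell$sd_mae, sqrt(sum((big$ms_ae - mean(big$ms_ae))^2) / 99),
               tolerance = 1e-12)
  expect_equal(cell$analysis_path, "MS")
})

test_that("the saturation rule scans means against the best window's CI bound", {
  cells <- tibble::tibble(
    model = "olslr", horizon = 1L, n_used = 5:12,
    n_eyes = 180L,
    mean_mae = c(3.0, 2.8, 2.5, 2.3, 2.2, 2.16, 2.15, 2.15),
    sd_mae = 1, se_mae = 1 / sqrt(180)
  )
  cells$ci_low <- cells$mean_mae - 1.96 * cells$se_mae
  cells$ci_high <- cells$mean_mae + 1.96 * cells$se_mae
  cells$ci_high[cells$n_used == 12] <- 2.29 # constructed bound at the best
  sat <- find_saturation(cells)
  expect_equal(sat$best_n_used, 12L) # tie at 2.15 broken toward longest
  expect_equal(sat$ci_upper, 2.29)
  expect_equal(sat$n_required, 9L) # first mean <= 2.29 is 2.2

  # all means within the bound: immediate saturation at 5
  flat <- cells
  flat$mean_mae <- rep(2.2, 8)
  flat$ci_high <- rep(2.25, 8)
  expect_equal(find_saturation(flat)$n_required, 5L)

  expect_error(find_saturation(cells[-2, ]), "missing windows")

  # randomized tables match an exhaustive scan oracle
  set.seed(22)
  for (i in 1:50) {
    tab <- cells
    tab$mean_mae <- sort(runif(8, 2, 4), decreasing = TRUE) +
      rnorm(8, 0, 0.05)
    tab$ci_high <- tab$mean_mae + runif(8, 0.05, 0.4)
    sat <- find_saturation(tab)
    best <- max(which(tab$mean_mae == min(tab$mean_mae)))
    hit <- tab$n_used[tab$mean_mae <= tab$ci_high[best]]
    expect_equal(sat$n_required, min(hit))
    expect_lte(sat$n_required, sat$best_n_used)
  }
})

test_that("MD slope equals an OLS fit to the extracted MD series", {
  norm <- normative_grid(33)
  s <- make_fixture("noise_free_linear", slope = -0.5, baseline = 25)
  expect_equal(md_slope(s, norm), -0.5, tolerance = 1e-10)
  expect_equal(md_slope(make_fixture("constant", level = 20), norm), 0)

  gen <- generate_cohort(synth_config(n_patients = 1L, n_eyes = 1L), seed = 31)
  s2 <- prepare_cohort(gen$cohort, quiet = TRUE)[[1]]
  md <- vapply(1:13, function(i) mean_deviation(s2, norm, i), numeric(1))
  expect_equal(md_slope(s2, norm),
               unname(fit_olslr(s2$time_years, md)$params["a"]),
               tolerance = 1e-12)
})

test_that("subgroup thresholds assign boundaries to the less severe group", {
  norm <- normative_grid(33)
  early <- make_fixture("constant", level = 14) # MD -19
  expect_equal(classify_subgroups(early, norm)$severity, "early_moderate")
  adv <- make_fixture("constant", level = 12) # MD -21
  expect_equal(classify_subgroups(adv, norm)$severity, "advanced")
  boundary <- make_fixture("constant", level = 13) # MD exactly -20
  expect_equal(classify_subgroups(boundary, norm)$severity, "early_moderate")

  prog <- make_fixture("noise_free_linear", slope = -0.30, baseline = 28)
  expect_equal(classify_subgroups(prog, norm)$progression, "progressive")
  stab <- make_fixture("noise_free_linear", slope = -0.10, baseline = 28)
  expect_equal(classify_subgroups(stab, norm)$progression, "stable")
})

test_that("the full experiment is deterministic and complete on a small cohort", {
  cohort <- linear_cohort(5)
  res <- run_experiment(cohort, models = "olslr", horizons = 1:3,
                        subgroups = FALSE)
  overall <- res$cells[res$cells$subgroup == "overall", ]
  expect_equal(nrow(overall), 2L * (8L + 7L + 6L)) # PW + MS paths
  expect_true(all(overall$mean_mae < 1e-9))
  expect_equal(res$saturation$n_required, rep(5L, 6L))

  res2 <- run_experiment(cohort, models = "olslr", horizons = 1:3,
                         subgroups = FALSE)
  expect_identical(res, res2)
})
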