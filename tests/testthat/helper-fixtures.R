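# Shared fixtures built in code.

# A small noise-free linear cohort: per-eye slopes/baselines chosen so no
# location reaches the 0 dB floor within 13 tests.
linear_cohort <- function(n_eyes = 5L, seed = 101L) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_eyes)) {
    id <- sprintf("lin%02d", i)
    out[[id]] <- make_fixture(
      "noise_free_linear",
      slope = runif(68, -1.2, -0.2),
      baseline = runif(68, 20, 34),
      eye_id = id, patient_id = sprintf("pat%02d", i)
    )
  }
  out
}

# Random small regression instances for oracle comparisons.
random_xy <- function(n = 5L) {
  x <- sort(runif(n, 0, 8))
  y <- runif(n, 0, 40)
  list(x = x, y = y)
}

# Independent normal-equation oracle: solve t(X) X beta = t(X) y directly.
normal_eq_fit <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1L]
}

# Brute-force step-up definition of Benjamini-Hochberg.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min((m / seq(i, m)) * ps[seq(i, m)]))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}
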