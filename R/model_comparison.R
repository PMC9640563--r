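#' Compare one model's errors against the reference in one evaluation cell
#'
#' Eyes are nested within patients (both eyes of a patient may be in the
#' cohort), so per-eye errors of the candidate model and of the reference
#' (OLSLR) are compared with a linear mixed model whose random effect is the
#' patient: the response is the per-eye error in long format (two rows per
#' eye), the fixed effect an indicator of the candidate model, and a random
#' intercept per patient absorbs the within-patient correlation. The estimate
#' is the fixed-effect coefficient (mean error difference, dB); the p-value is
#' the Wald-type t-test of that coefficient with Satterthwaite degrees of
#' freedom. In the balanced one-eye-per-patient case this reduces to a paired
#' t-test.
#'
#' @param err_candidate,err_reference Per-eye errors (same eyes, same order).
#' @param eye_id Eye identifiers.
#' @param patient_id Patient identifiers aligned with `eye_id`.
#' @return A list with `estimate` (candidate minus reference, dB), `p`
#'   and `converged`.
#' @export
compare_cell <- function(err_candidate, err_reference, eye_id, patient_id) {
  n <- length(eye_id)
  stopifnot(length(err_candidate) == n, length(err_reference) == n,
            length(patient_id) == n)
  if (length(unique(patient_id)) < 3L) {
    stop("insufficient data: need at least 3 patients", call. = FALSE)
  }
  df <- data.frame(
    err = c(err_reference, err_candidate),
    candidate = rep(c(0, 1), each = n),
    eye = rep(eye_id, 2L),
    patient = rep(patient_id, 2L)
  )
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(err ~ candidate + (1 | patient), data = df,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(estimate = mean(err_candidate) - mean(err_reference),
                p = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(summary(fit))
  list(estimate = unname(cf["candidate", "Estimate"]),
       p = unname(cf["candidate", "Pr(>|t|)"]),
       converged = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values (wrapper
#' around [stats::p.adjust()] with input validation).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Compare every candidate model against the reference across all cells
#'
#' For each combination of analysis path, subgroup, horizon, window length and
#' candidate model, runs [compare_cell()] on the per-eye errors, then applies
#' Benjamini-Hochberg correction within each family -- one family per
#' (horizon, path, subgroup), pooling all candidate models and window lengths,
#' matching the organization of one comparison table per horizon. Significance
#' is an adjusted p below `alpha`.
#'
#' @param experiment Output of [run_experiment()] (needs `outcomes` and
#'   `subgroups`).
#' @param reference Reference model (default `"olslr"`).
#' @param alpha Significance level (default 0.05).
#' @param subgroups Also compare within severity / progression subgroups?
#' @return A tibble: `analysis_path, subgroup, horizon, n_used, model,
#'   estimate, p_raw, p_adjusted, significant`.
#' @export
compare_all <- function(experiment, reference = "olslr", alpha = 0.05,
                        subgroups = TRUE) {
  outcomes <- experiment$outcomes
  labels <- experiment$subgroups
  candidates <- setdiff(unique(outcomes$model), reference)
  if (!length(candidates)) {
    stop("no candidate models beyond the reference", call. = FALSE)
  }
  outcomes <- dplyr::left_join(
    outcomes, labels[, c("eye_id", "severity", "progression")], by = "eye_id"
  )
  subgroup_of <- function(df, sub) {
    if (sub == "overall") df
    else df[df$severity == sub | df$progression == sub, , drop = FALSE]
  }
  subgroup_levels <- if (subgroups) {
    c("overall",
      intersect(c("early_moderate", "advanced"), labels$severity),
      intersect(c("stable", "progressive"), labels$progression))
  } else "overall"

  rows <- list()
  for (path in c("PW", "MS")) {
    vcol <- if (path == "PW") "mae" else "ms_ae"
    for (sub in unique(subgroup_levels)) {
      d_sub <- subgroup_of(outcomes, sub)
      for (h in sort(unique(d_sub$horizon))) {
        fam <- list()
        d_h <- d_sub[d_sub$horizon == h, , drop = FALSE]
        for (m in candidates) {
          for (w in sort(unique(d_h$n_used))) {
            ref <- d_h[d_h$model == reference & d_h$n_used == w, , drop = FALSE]
            cand <- d_h[d_h$model == m & d_h$n_used == w, , drop = FALSE]
            cand <- cand[match(ref$eye_id, cand$eye_id), , drop = FALSE]
            cc <- compare_cell(cand[[vcol]], ref[[vcol]],
                               ref$eye_id, ref$patient_id)
            fam[[length(fam) + 1L]] <- tibble::tibble(
              analysis_path = path, subgroup = sub,
              horizon = as.integer(h), n_used = as.integer(w), model = m,
              estimate = cc$estimate, p_raw = cc$p
            )
          }
        }
        fam <- dplyr::bind_rows(fam)
        fam$p_adjusted <- bh_adjust(fam$p_raw)
        fam$significant <- !is.na(fam$p_adjusted) & fam$p_adjusted < alpha
        rows[[length(rows) + 1L]] <- fam
      }
    }
  }
  dplyr::bind_rows(rows)
}
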