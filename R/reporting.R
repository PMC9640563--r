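#' Plot mean error against window length
#'
#' Reproduces the standard accuracy-versus-number-of-tests display: one line
#' per model, faceted by horizon, with a dashed horizontal line at the
#' reference model's best-window CI upper bound (the saturation level).
#'
#' @param cells [aggregate_outcomes()] output (one analysis path).
#' @param saturation Matching [find_saturation()] rows (optional).
#' @return A ggplot object.
#' @export
plot_mae_curves <- function(cells, saturation = NULL) {
  p <- ggplot2::ggplot(
    cells,
    ggplot2::aes(x = .data$n_used, y = .data$mean_mae, colour = .data$model)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_wrap(~horizon, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Number of tests used", y = "Mean absolute error (dB)",
                  colour = "Model") +
    ggplot2::theme_minimal()
  if (!is.null(saturation)) {
    p <- p + ggplot2::geom_hline(
      data = saturation, ggplot2::aes(yintercept = .data$ci_upper),
      linetype = "dashed", colour = "grey30"
    )
  }
  p
}

read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

write_manifest <- function(dir, command, config) {
  config_no_seed <- config
  manifest <- list(
    command = command,
    config = config,
    config_hash = rlang::hash(config_no_seed),
    package_version = as.character(utils::packageVersion("vftrend"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Generate and save a synthetic cohort
#'
#' Builds a [synth_config()] from a YAML file (fields as in `synth_config`),
#' generates the cohort, writes `cohort.csv`, `truth.csv`, `truth_eye.csv`,
#' `normative.csv` and a manifest, and prints a demographics-style summary.
#'
#' @param config Path to a YAML config, or a `synth_config` object.
#' @param out Output directory.
#' @param seed Optional seed override.
#' @param quiet Suppress the summary printout.
#' @return The generated bundle, invisibly.
#' @export
cmd_simulate <- function(config = synth_config(), out, seed = NULL,
                         quiet = FALSE) {
  if (is.character(config)) {
    fields <- read_run_config(config)
    config <- do.call(synth_config, fields)
  }
  gen <- generate_cohort(config, seed = seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_cohort(gen, out)
  write_manifest(out, "simulate", unclass(config))

  prepared <- prepare_cohort(gen$cohort, quiet = TRUE)
  labels <- dplyr::bind_rows(lapply(prepared, classify_subgroups,
                                    norm = gen$norm))
  fu <- vapply(prepared, function(s) max(s$time_years), numeric(1))
  if (!quiet) {
    cat(sprintf("Synthetic cohort: %d eyes / %d patients\n",
                length(prepared), length(unique(labels$patient_id))))
    cat(sprintf("  Initial MD, mean +- SD, dB: %.1f +- %.1f\n",
                mean(labels$initial_md), stats::sd(labels$initial_md)))
    cat(sprintf("  MD slope, mean +- SD, dB/year: %.2f +- %.2f\n",
                mean(labels$md_slope), stats::sd(labels$md_slope)))
    cat(sprintf("  Time from 1st to 13th test, mean +- SD, years: %.1f +- %.1f\n",
                mean(fu), stats::sd(fu)))
  }
  invisible(gen)
}

#' Run the rolling-prediction evaluation on a cohort file
#'
#' Reads a long-format cohort CSV, prepares eligible eyes, runs
#' [run_experiment()], and writes `outcomes.csv`, `eval_cells.csv`,
#' `saturation.csv`, the MAE-versus-window plots per analysis path, and a
#' manifest.
#'
#' @param cohort_csv Path to the long-format cohort CSV.
#' @param out Output directory.
#' @param models Models to evaluate (reference `"olslr"` always included).
#' @param horizons Horizons (subset of 1:3).
#' @param clamp Truncate predictions into `[0, 40]` dB?
#' @param subgroups Aggregate within severity / progression subgroups too?
#' @param normative_csv Optional normative grid CSV (default: flat 33 dB).
#' @return The [run_experiment()] bundle, invisibly.
#' @export
cmd_evaluate <- function(cohort_csv, out, models = model_kinds(),
                         horizons = 1:3, clamp = FALSE, subgroups = TRUE,
                         normative_csv = NULL) {
  if (!file.exists(cohort_csv)) {
    stop("cohort file not found: ", cohort_csv, call. = FALSE)
  }
  norm <- if (is.null(normative_csv)) normative_grid()
          else read_normative_csv(normative_csv)
  raw <- read_series_csv(cohort_csv)
  prepared <- prepare_cohort(raw)
  res <- run_experiment(prepared, models = models, horizons = horizons,
                        norm = norm, clamp = clamp, subgroups = subgroups)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$outcomes, file.path(out, "outcomes.csv"))
  readr::write_csv(res$cells, file.path(out, "eval_cells.csv"))
  readr::write_csv(res$saturation, file.path(out, "saturation.csv"))
  readr::write_csv(res$subgroups, file.path(out, "subgroups.csv"))
  for (path in c("PW", "MS")) {
    cells <- res$cells[res$cells$analysis_path == path &
                         res$cells$subgroup == "overall", ]
    sat <- res$saturation[res$saturation$analysis_path == path, ]
    p <- plot_mae_curves(cells, sat)
    for (ext in c("png", "pdf")) {
      ggplot2::ggsave(
        file.path(out, sprintf("mae_%s.%s", tolower(path), ext)),
        p, width = 9, height = 3.2, dpi = 150
      )
    }
  }
  write_manifest(out, "evaluate",
                 list(models = models, horizons = horizons, clamp = clamp,
                      subgroups = subgroups))
  invisible(res)
}

#' Compare models against the reference on saved evaluation outcomes
#'
#' Reads `outcomes.csv` and `subgroups.csv` from an evaluation directory, runs
#' [compare_all()] and writes `comparisons.csv`.
#'
#' @param eval_dir Directory written by [cmd_evaluate()].
#' @param out Output directory (default: `eval_dir`).
#' @param alpha Significance level.
#' @return The comparison tibble, invisibly.
#' @export
cmd_compare <- function(eval_dir, out = eval_dir, alpha = 0.05) {
  oc_path <- file.path(eval_dir, "outcomes.csv")
  sg_path <- file.path(eval_dir, "subgroups.csv")
  if (!file.exists(oc_path) || !file.exists(sg_path)) {
    stop("evaluation outputs not found in ", eval_dir,
         " (run cmd_evaluate first)", call. = FALSE)
  }
  experiment <- list(
    outcomes = readr::read_csv(oc_path, show_col_types = FALSE, progress = FALSE),
    subgroups = readr::read_csv(sg_path, show_col_types = FALSE, progress = FALSE)
  )
  cmp <- compare_all(experiment, alpha = alpha)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cmp, file.path(out, "comparisons.csv"))
  write_manifest(out, "compare", list(alpha = alpha))
  invisible(cmp)
}
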