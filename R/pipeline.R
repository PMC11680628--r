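#' Pipeline configuration
#'
#' Bundles every stage's settings into one serializable object; a run
#' writes its resolved configuration (plus a content hash) beside its
#' outputs so reruns are byte-comparable.
#'
#' @param trials_csv Path to the canonical trial CSV (or NULL to simulate).
#' @param out_dir Output directory for the run.
#' @param simulate Optional list for synthetic input: `n_participants`,
#'   and optionally `design` ([experiment_design()]) and `population`
#'   ([population_spec()]).
#' @param rt_floor,rt_ceiling,fast_fraction,slope_tolerance,manual_exclude
#'   Preprocessing settings (see [preprocess_trials()]).
#' @param mcmc An [mcmc_config()].
#' @param k Cluster count for the threshold clustering.
#' @param seed Global seed (drives simulation; the sampler uses
#'   `mcmc$seed`).
#' @return List of class `quant_pipeline_config`.
#' @export
pipeline_config <- function(trials_csv = NULL, out_dir,
                            simulate = NULL,
                            rt_floor = 300, rt_ceiling = 2500,
                            fast_fraction = 0.5, slope_tolerance = 0,
                            manual_exclude = character(),
                            mcmc = mcmc_config(), k = 4, seed = 1) {
  if (is.null(trials_csv) && is.null(simulate)) {
    stop("Provide either `trials_csv` or a `simulate` block.", call. = FALSE)
  }
  structure(list(trials_csv = trials_csv, out_dir = out_dir, simulate = simulate,
                 rt_floor = rt_floor, rt_ceiling = rt_ceiling,
                 fast_fraction = fast_fraction, slope_tolerance = slope_tolerance,
                 manual_exclude = manual_exclude, mcmc = mcmc, k = k, seed = seed),
            class = "quant_pipeline_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> preprocess -> fit -> analyze, writing
#' every stage's serialized output into `config$out_dir`: the resolved
#' configuration with its hash, the (simulated or copied) trial CSV, the
#' preprocessing report, posterior summaries and convergence report, and
#' the downstream cluster/test/correlation tables. Stages communicate only
#' through these files' in-memory equivalents, and row counts in/out of
#' every stage are logged via `message()`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results (`trials`, `report`,
#'   `fit`, `clusters`, `ordering`, `wilks`, `lda`, `correlations`,
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "quant_pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  resolved <- unclass(config)
  resolved$hash <- config_hash(config)
  resolved$mcmc <- unclass(resolved$mcmc)
  jsonlite::write_json(resolved[setdiff(names(resolved), c("simulate"))],
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    design <- sim$design %||% experiment_design()
    pop <- sim$population %||% population_spec()
    params <- draw_population(pop, sim$n_participants, seed = config$seed)
    trials <- simulate_trials(design, params, seed = config$seed + 1)
    write_trials(trials, file.path(out, "trials.csv"))
    write_truth(params, pop, file.path(out, "truth.json"))
  } else {
    trials <- read_trials(config$trials_csv)
  }
  message("pipeline: ", nrow(trials), " trials in")

  pp <- preprocess_trials(trials, rt_floor = config$rt_floor,
                          rt_ceiling = config$rt_ceiling,
                          fast_fraction = config$fast_fraction,
                          slope_tolerance = config$slope_tolerance,
                          manual_exclude = config$manual_exclude)
  write_preprocess_report(pp$report, file.path(out, "preprocess_report.json"))
  write_trials(pp$trials, file.path(out, "trials_clean.csv"))
  message("pipeline: ", nrow(pp$trials), " trials after preprocessing (",
          length(unique(pp$trials$participant_id)), " participants)")

  fit <- fit_quantifier_model(pp$trials, config$mcmc)
  write_posterior_summary(fit, file.path(out, "posterior_summary.csv"))
  write_convergence(fit, file.path(out, "convergence.json"))

  tm <- threshold_matrix(fit)
  results <- list(trials = trials, report = pp$report, fit = fit, out_dir = out)

  if (ncol(tm) - 1 >= 2) {
    results$ordering <- ordering_test(tm)
  }
  k <- min(config$k, nrow(tm))
  results$clusters <- cluster_thresholds(tm, k = k)
  write_cluster_table(results$clusters, file.path(out, "cluster_table.csv"))

  if (k >= 2 && all(table(results$clusters$labels) >= 2)) {
    results$wilks <- wilks_stepwise(tm, results$clusters$labels)
    if (nrow(results$wilks)) {
      results$lda <- lda_validate(tm, results$clusters$labels,
                                  variables = results$wilks$variable)
    } else {
      message("pipeline: no variable passed stepwise selection; LDA skipped")
    }
  } else {
    message("pipeline: k = ", k,
            " leaves no separable clusters; stepwise selection and LDA skipped")
  }
  if (!is.null(results$ordering)) {
    write_test_report(results$ordering, results$lda, results$wilks,
                      path = file.path(out, "test_report.json"))
  }
  results$correlations <- param_correlations(posterior_means(fit))
  write_correlations(results$correlations, file.path(out, "correlations.csv"))
  make_report(results, file.path(out, "report.md"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_tbl <- function(df, digits = 3) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~ signif(.x, digits)))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Write a human-readable markdown report for a pipeline run
#'
#' Summarizes the run: preprocessing counts; a group-level parameter table
#' (mean and SD of threshold, vagueness and response error per quantifier,
#' thresholds also on the percent scale); ordering-test results; the
#' cluster table; and LDA validation, mirroring how such analyses are
#' conventionally reported.
#'
#' @param results The list returned by [run_pipeline()].
#' @param path Output markdown path.
#' @return `path`, invisibly.
#' @export
make_report <- function(results, path) {
  fit <- results$fit
  pm <- posterior_means(fit)
  group <- pm |>
    dplyr::group_by(.data$quantifier) |>
    dplyr::summarise(
      threshold = mean(.data$beta), threshold_sd = sd(.data$beta),
      percent = threshold_to_percent(mean(.data$beta)),
      vagueness = mean(.data$alpha), vagueness_sd = sd(.data$alpha),
      response_error = mean(.data$gamma), response_error_sd = sd(.data$gamma),
      .groups = "drop") |>
    dplyr::arrange(match(.data$quantifier, quantifier_levels()))
  fr <- results$report$trial_exclusion_fractions
  lines <- c(
    "# Quantifier threshold analysis run", "",
    paste0("Participants analysed: ", length(fit$participants),
           "; quantifiers: ", length(fit$quantifiers),
           "; trials fitted: ", fit$n_trials, "."), "",
    "## Preprocessing", "",
    paste0("- fast-guess participants excluded: ",
           length(results$report$excluded_fast_participants)),
    paste0("- non-monotone participants excluded: ",
           length(results$report$excluded_nonmonotonic_participants)),
    paste0("- manually excluded: ",
           length(results$report$excluded_manual_participants)),
    sprintf("- trials removed: %.1f%% fast, %.1f%% slow (%.1f%% total)",
            100 * fr$fast, 100 * fr$slow, 100 * fr$total), "",
    "## Group-level parameters (mean posterior estimates across participants)",
    "", fmt_tbl(group), ""
  )
  if (!is.null(results$ordering)) {
    o <- results$ordering
    lines <- c(lines, "## Threshold ordering", "",
               sprintf("Friedman chi^2(%d) = %.1f, p = %.3g; Kendall's W = %.2f.",
                       o$friedman$df, o$friedman$statistic, o$friedman$p,
                       o$kendall_w), "",
               fmt_tbl(o$pairwise), "")
  }
  if (!is.null(results$clusters)) {
    lines <- c(lines, "## Threshold clusters (Ward, ward.D2)", "",
               paste0("Cut at k = ", results$clusters$k, "; sizes ",
                      paste(table(results$clusters$labels), collapse = "/"), "."),
               "", fmt_tbl(results$clusters$summary), "")
  }
  if (!is.null(results$lda)) {
    lines <- c(lines, "## Discriminant validation", "",
               paste0("Stepwise Wilks selection: ",
                      paste(results$wilks$variable, collapse = ", "), "."),
               sprintf("LDA accuracy %.1f%% (resubstitution), %.1f%% (leave-one-out).",
                       100 * results$lda$accuracy_resub,
                       100 * results$lda$accuracy_loo), "")
  }
  if (!is.null(results$correlations)) {
    lines <- c(lines, "## Parameter correlations", "",
               fmt_tbl(results$correlations), "")
  }
  writeLines(lines, path)
  invisible(path)
}
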