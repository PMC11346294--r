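#' End-to-end analysis pipeline
#'
#' Three orchestration stages mirror the analysis workflow:
#' [simulate_cohort()] writes a generated cohort to disk,
#' [run_growth_analysis()] filters, fits, extracts features and runs the
#' sensitivity sweep, and [run_evaluation()] produces the per-feature
#' discrimination report and the optional multivariable score. The
#' combined [run_report()] wraps all stages and [write_report()] exports
#' the report tables (CSV) and records (JSON).
#'
#' @name pipeline
NULL

#' Simulate a cohort to a file
#'
#' @param spec A `cohort_spec`, or a fixture name understood by
#'   [generate_fixture()].
#' @param seed RNG seed.
#' @param path Output CSV/TSV path.
#' @param spec_path Optional path for a JSON echo of the spec.
#' @return The cohort tibble, invisibly.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1, path,
                            spec_path = NULL) {
  cohort <- if (is.character(spec)) {
    generate_fixture(spec, seed = seed)
  } else {
    generate_cohort(spec, seed = seed)
  }
  write_cohort(cohort, path)
  if (!is.null(spec_path) && inherits(spec, "cohort_spec")) {
    write_cohort_spec(spec, spec_path)
  }
  invisible(cohort)
}

#' Filter, fit and characterise a cohort
#'
#' @param cohort A cohort tibble (or a path readable by [read_cohort()]).
#' @param min_scans,require_increase,min_fold_increase Passed to
#'   [inclusion_filter()].
#' @param fit_method Passed to [fit_growth()] / [compute_features()].
#' @param n_reps,epsilon,threshold Sensitivity parameters (see
#'   [cohort_sensitivity()]); `n_reps = 0` skips the sensitivity sweep.
#' @param seed Seed for the sensitivity sweep.
#' @return A list of class `growth_analysis`: `filter`
#'   (`inclusion_result`), `fits`, `category_table`, `features`,
#'   `sensitivity` (or `NULL`), `config`.
#' @export
run_growth_analysis <- function(cohort, min_scans = 3,
                                require_increase = TRUE,
                                min_fold_increase = 1.0,
                                fit_method = c("exact3", "least_squares"),
                                n_reps = 200, epsilon = 0.05,
                                threshold = 0.5, seed = 1) {
  fit_method <- match.arg(fit_method)
  if (is.character(cohort) && length(cohort) == 1) {
    cohort <- read_cohort(cohort)
  }
  flt <- inclusion_filter(cohort, min_scans = min_scans,
                          require_increase = require_increase,
                          min_fold_increase = min_fold_increase)
  if (nrow(flt$retained) == 0) {
    stop_validation("No nodules remain after the inclusion filter.")
  }
  fits <- fit_growth(flt$retained, method = fit_method)
  features <- compute_features(flt$retained, fit_method = fit_method)
  sens <- NULL
  if (n_reps > 0) {
    sens <- cohort_sensitivity(flt$retained, n_reps = n_reps,
                               epsilon = epsilon, threshold = threshold,
                               seed = seed)
  }
  structure(
    list(filter = flt, fits = fits, category_table = category_table(fits),
         features = features, sensitivity = sens,
         config = list(min_scans = min_scans,
                       require_increase = require_increase,
                       min_fold_increase = min_fold_increase,
                       fit_method = fit_method, n_reps = n_reps,
                       epsilon = epsilon, threshold = threshold,
                       seed = seed)),
    class = "growth_analysis")
}

#' @export
print.growth_analysis <- function(x, ...) {
  print(x$filter)
  cat("\nGrowth categories by malignancy:\n")
  print(x$category_table)
  if (!is.null(x$sensitivity)) {
    ok <- x$sensitivity$robust
    cat(sprintf("\nSensitivity: %d/%d nodules robust (|median(beta*) - beta| < %g)\n",
                sum(ok, na.rm = TRUE), length(ok), x$config$threshold))
  }
  invisible(x)
}

#' Discrimination report for a feature matrix
#'
#' @param features Tibble from [compute_features()] (with labels).
#' @param feature_cols Features to evaluate; default
#'   [discrimination_features()].
#' @param multivariable Optional character vector of candidate terms for
#'   [multivariable_score()] (e.g. `c("nu_02", "morphology")`); `NULL`
#'   skips it.
#' @param p_stay Wald elimination threshold for the multivariable model;
#'   `p_stay = 1` forces entry of every candidate.
#' @param label_col Label column name.
#' @return A list of class `evaluation_report`: `evaluations` (tibble),
#'   `multivariable` (or `NULL`), `normality` (screening tibble).
#' @export
run_evaluation <- function(features, feature_cols = NULL,
                           multivariable = NULL, p_stay = 0.05,
                           label_col = "malignancy") {
  evals <- evaluate_features(features, feature_cols = feature_cols,
                             label_col = label_col)
  mv <- NULL
  if (!is.null(multivariable)) {
    mv <- multivariable_score(features, multivariable,
                              label_col = label_col, p_stay = p_stay)
  }
  norm <- normality_screen(features,
                           cols = intersect(feature_cols %||%
                                              discrimination_features(),
                                            names(features)))
  structure(list(evaluations = evals, multivariable = mv, normality = norm),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Per-feature discrimination (benign vs malignant):\n")
  print(dplyr::select(x$evaluations, "feature", "auc", "sensitivity",
                      "specificity"), n = Inf)
  if (!is.null(x$multivariable)) {
    cat("\n")
    print(x$multivariable)
  }
  invisible(x)
}

#' Run the full pipeline on a cohort
#'
#' @inheritParams run_growth_analysis
#' @inheritParams run_evaluation
#' @return A list of class `nodule_report` combining the
#'   `growth_analysis` and `evaluation_report` pieces plus the seed and
#'   configuration.
#' @export
run_report <- function(cohort, min_scans = 3, require_increase = TRUE,
                       min_fold_increase = 1.0,
                       fit_method = c("exact3", "least_squares"),
                       n_reps = 200, epsilon = 0.05, threshold = 0.5,
                       seed = 1, feature_cols = NULL,
                       multivariable = c("nu_02", "morphology"),
                       p_stay = 0.05) {
  ga <- run_growth_analysis(cohort, min_scans = min_scans,
                            require_increase = require_increase,
                            min_fold_increase = min_fold_increase,
                            fit_method = fit_method, n_reps = n_reps,
                            epsilon = epsilon, threshold = threshold,
                            seed = seed)
  ev <- run_evaluation(ga$features, feature_cols = feature_cols,
                       multivariable = multivariable, p_stay = p_stay)
  structure(c(unclass(ga), unclass(ev)), class = "nodule_report")
}

#' @export
print.nodule_report <- function(x, ...) {
  print.growth_analysis(x, ...)
  cat("\n")
  print.evaluation_report(x, ...)
  invisible(x)
}

#' Write report artifacts to a directory
#'
#' Writes `fits.csv`, `features.csv`, `category_table.csv`,
#' `evaluations.csv` (Table-3-style layout), `sensitivity.json`,
#' `exclusions.json` and `report.json` (configuration echo, seed and
#' summary). Numeric fields in JSON summaries are rounded to 6
#' significant digits for hash-stable output.
#'
#' @param report A `nodule_report` from [run_report()].
#' @param dir Output directory (created if needed).
#' @param digits Significant digits for JSON summary rounding.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, digits = 6) {
  stopifnot(inherits(report, "nodule_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$fits, file.path(dir, "fits.csv"), progress = FALSE)
  write_features(report$features, file.path(dir, "features.csv"))
  readr::write_csv(report$category_table,
                   file.path(dir, "category_table.csv"), progress = FALSE)
  readr::write_csv(
    dplyr::select(report$evaluations, -"roc"),
    file.path(dir, "evaluations.csv"), progress = FALSE)
  write_exclusion_log(report$filter, file.path(dir, "exclusions.json"))
  if (!is.null(report$sensitivity)) {
    write_sensitivity(report$sensitivity, file.path(dir, "sensitivity.json"))
  }
  summary <- list(
    config = report$config,
    n_retained = sum(report$filter$log$retained),
    n_excluded = sum(!report$filter$log$retained),
    fraction_robust = if (is.null(report$sensitivity)) NULL else
      signif(mean(report$sensitivity$robust, na.rm = TRUE), digits),
    auc = setNames(as.list(signif(report$evaluations$auc, digits)),
                   report$evaluations$feature),
    multivariable_auc = if (is.null(report$multivariable) ||
                              isTRUE(report$multivariable$degenerate)) NULL else
      signif(report$multivariable$eval$auc, digits))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
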