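#' Longitudinal nodule cohorts
#'
#' A cohort is a long-format tibble with one row per CT observation of a
#' nodule. Required columns: `nodule_id` (character), `malignancy`
#' (`"benign"` or `"malignant"`), `morphology` (`"solid"`, `"part_solid"`,
#' `"non_solid"` or `"unknown"`), `time_months` (months since the nodule's
#' first scan, first scan at 0), `volume_mm3` (segmented volume, positive).
#' Optional columns: `histology`, `stage`, `attenuation_hu` (mean CT
#' attenuation in Hounsfield Units; `NA` when not measured).
#'
#' @name cohort
NULL

.cohort_required <- c("nodule_id", "malignancy", "morphology",
                      "time_months", "volume_mm3")
.cohort_optional <- c("histology", "stage", "attenuation_hu")
.cohort_cols <- c("nodule_id", "malignancy", "morphology", "histology",
                  "stage", "time_months", "volume_mm3", "attenuation_hu")
.morphology_levels <- c("solid", "part_solid", "non_solid", "unknown")

#' Normalise and validate a cohort table
#'
#' Fills in optional columns, orders observations by nodule and time,
#' re-bases each nodule's times so its earliest scan is at 0 (when
#' `rebase = TRUE`), and enforces the cohort invariants: positive volumes,
#' non-negative times, no duplicate (nodule, time) pairs, known
#' malignancy/morphology labels.
#'
#' @param x A data frame with the columns described in [cohort].
#' @param rebase Re-base each nodule's times so the earliest is 0.
#' @return A validated cohort tibble.
#' @export
as_cohort <- function(x, rebase = TRUE) {
  if (!is.data.frame(x)) stop_validation("A cohort must be a data frame.")
  missing_cols <- setdiff(.cohort_required, names(x))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("Missing required column(s): %s.",
                            paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  for (col in .cohort_optional) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x$nodule_id <- as.character(x$nodule_id)
  x$histology <- as.character(x$histology)
  x$stage <- as.character(x$stage)
  for (col in c("time_months", "volume_mm3", "attenuation_hu")) {
    if (!is.numeric(x[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[col]]))) &
                     !is.na(x[[col]]))
      if (length(bad) > 0) {
        stop_validation(sprintf(
          "Column `%s` is not numeric (first offending row: %d).",
          col, bad[1]))
      }
      x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
    }
  }
  if (anyNA(x$time_months) || anyNA(x$volume_mm3)) {
    stop_validation("`time_months` and `volume_mm3` must not contain NA.")
  }
  if (any(x$volume_mm3 <= 0)) {
    bad <- which(x$volume_mm3 <= 0)[1]
    stop_validation(sprintf(
      "`volume_mm3` must be positive (row %d has %g).", bad, x$volume_mm3[bad]))
  }
  bad_mal <- setdiff(unique(x$malignancy), c("benign", "malignant"))
  if (length(bad_mal) > 0) {
    stop_validation(sprintf("Unknown malignancy label(s): %s.",
                            paste(bad_mal, collapse = ", ")))
  }
  bad_morph <- setdiff(unique(x$morphology), .morphology_levels)
  if (length(bad_morph) > 0) {
    stop_validation(sprintf("Unknown morphology label(s): %s.",
                            paste(bad_morph, collapse = ", ")))
  }
  x <- dplyr::arrange(x, .data$nodule_id, .data$time_months)
  if (rebase) {
    x <- dplyr::mutate(x,
      time_months = .data$time_months - min(.data$time_months),
      .by = "nodule_id")
  }
  if (any(x$time_months < 0)) {
    stop_validation("`time_months` must be non-negative.")
  }
  dup <- duplicated(x[c("nodule_id", "time_months")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_validation(sprintf(
      "Duplicate (nodule_id, time_months) pair for nodule '%s' at %g months.",
      x$nodule_id[i], x$time_months[i]))
  }
  # consistent per-nodule labels
  lab <- dplyr::summarise(x,
    n_mal = dplyr::n_distinct(.data$malignancy),
    n_mor = dplyr::n_distinct(.data$morphology),
    .by = "nodule_id")
  if (any(lab$n_mal > 1) || any(lab$n_mor > 1)) {
    stop_validation("Per-nodule labels (malignancy, morphology) must be constant.")
  }
  x[.cohort_cols]
}

#' Read a cohort table from CSV or TSV
#'
#' @param path Path to a delimited file in the long format of [cohort].
#' @param dialect `"auto"` (by extension: `.tsv`/`.tab` means tab),
#'   `"csv"`, or `"tsv"`.
#' @param time_unit Unit of the time column in the file; `"days"` is
#'   converted to months at 30.4375 days/month.
#' @return A validated cohort tibble (times re-based to 0 per nodule).
#' @export
read_cohort <- function(path, dialect = c("auto", "csv", "tsv"),
                        time_unit = c("months", "days")) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop_validation(sprintf("File not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  missing_cols <- setdiff(.cohort_required, names(raw))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("Missing required column(s): %s.",
                            paste(missing_cols, collapse = ", ")))
  }
  for (col in c("time_months", "volume_mm3", "attenuation_hu")) {
    if (!col %in% names(raw)) next
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "Non-numeric value '%s' in column `%s` (data row %d).",
        raw[[col]][bad[1]], col, bad[1]))
    }
    raw[[col]] <- num
  }
  if (time_unit == "days") raw$time_months <- days_to_months(raw$time_months)
  as_cohort(raw)
}

#' Write a cohort table to CSV or TSV
#'
#' Writes the long format read by [read_cohort()], rows ordered by
#' `nodule_id` then `time_months`, so the output is deterministic.
#'
#' @param cohort A cohort tibble.
#' @param path Output path; a `.tsv`/`.tab` extension selects tabs.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort, rebase = FALSE)
  cohort <- dplyr::arrange(cohort, .data$nodule_id, .data$time_months)
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) {
    readr::write_tsv(cohort, path, progress = FALSE)
  } else {
    readr::write_csv(cohort, path, progress = FALSE)
  }
  invisible(path)
}

#' Apply the study inclusion filter
#'
#' Retains nodules with at least `min_scans` observations whose volumes,
#' over the first `min_scans` scans, increase strictly with a fold change
#' of at least `min_fold_increase` (last/first). Later observations are
#' not used for exclusion, but a nodule whose later volumes break
#' monotonicity is flagged in the log.
#'
#' @param cohort A cohort tibble.
#' @param min_scans Minimum number of scans (>= 2) required.
#' @param require_increase Require strictly increasing volumes across the
#'   first `min_scans` scans.
#' @param min_fold_increase Minimum ratio of the `min_scans`-th volume to
#'   the baseline volume (1 = monotonicity only).
#' @return A list of class `inclusion_result` with elements
#'   `retained` (cohort tibble of retained nodules) and `log` (tibble with
#'   one row per input nodule: `nodule_id`, `retained`, `reason` in
#'   `{too_few_scans, non_increasing, non_positive_volume}` or `NA`, and
#'   `later_nonmonotone` flag).
#' @export
inclusion_filter <- function(cohort, min_scans = 3, require_increase = TRUE,
                             min_fold_increase = 1.0) {
  if (min_scans < 2) stop_param("`min_scans` must be at least 2.")
  cohort <- as_cohort(cohort, rebase = FALSE)
  per <- dplyr::summarise(cohort,
    n_scans = dplyr::n(),
    reason = {
      v <- .data$volume_mm3[order(.data$time_months)]
      if (any(v <= 0)) "non_positive_volume"
      else if (dplyr::n() < min_scans) "too_few_scans"
      else if (require_increase &&
               (any(diff(v[seq_len(min_scans)]) <= 0) ||
                v[min_scans] / v[1] < min_fold_increase)) "non_increasing"
      else NA_character_
    },
    later_nonmonotone = {
      v <- .data$volume_mm3[order(.data$time_months)]
      dplyr::n() > min_scans && any(diff(v[-seq_len(min_scans - 1)]) <= 0)
    },
    .by = "nodule_id")
  log <- tibble::tibble(
    nodule_id = per$nodule_id,
    retained = is.na(per$reason),
    reason = per$reason,
    later_nonmonotone = per$later_nonmonotone & is.na(per$reason)
  )
  retained <- dplyr::filter(cohort,
    .data$nodule_id %in% log$nodule_id[log$retained])
  structure(list(retained = retained, log = log),
            class = "inclusion_result")
}

#' @export
print.inclusion_result <- function(x, ...) {
  n_in <- nrow(x$log)
  n_keep <- sum(x$log$retained)
  cat(sprintf("Inclusion filter: %d of %d nodule(s) retained\n", n_keep, n_in))
  if (n_keep < n_in) {
    tab <- table(x$log$reason[!x$log$retained])
    for (r in names(tab)) cat(sprintf("  excluded (%s): %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Write an exclusion log as JSON
#'
#' @param result An `inclusion_result` from [inclusion_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(result, path) {
  stopifnot(inherits(result, "inclusion_result"))
  jsonlite::write_json(result$log, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
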