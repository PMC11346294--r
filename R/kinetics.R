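#' Growth-rate and doubling-time estimators
#'
#' Candidate discriminators computed from the first three scans of each
#' nodule: pairwise linear rates `nu_if = (V_f - V_i) / dt` (mm^3/month),
#' pairwise exponential rates `lambda_if = (ln V_f - ln V_i) / dt`
#' (1/month), their three-point least-squares analogues, the modified
#' Schwartz volume doubling time `VDT_exp = ln2 / lambda_01`, the
#' scaling-law doubling time `VDT_beta`, and the baseline volume,
#' attenuation and lesion mass.
#'
#' @name kinetics
NULL

#' Pairwise linear growth rate
#'
#' @param v_i,v_f Initial and final volumes (mm^3).
#' @param dt Time interval in months (positive).
#' @return Rate in mm^3/month; sign follows `v_f - v_i`.
#' @examples
#' linear_rate(100, 340, 24) # 10
#' @export
linear_rate <- function(v_i, v_f, dt) {
  if (any(dt <= 0)) stop_domain("`dt` must be positive.")
  (v_f - v_i) / dt
}

#' Pairwise exponential growth rate
#'
#' Natural-log based, so that `VDT = ln2 / lambda` is exact.
#'
#' @inheritParams linear_rate
#' @return Rate in 1/month.
#' @examples
#' exp_rate(100, 200, 12) # log(2)/12
#' @export
exp_rate <- function(v_i, v_f, dt) {
  if (any(dt <= 0)) stop_domain("`dt` must be positive.")
  if (any(v_i <= 0) || any(v_f <= 0)) {
    stop_domain("Volumes must be positive.")
  }
  (log(v_f) - log(v_i)) / dt
}

#' Least-squares growth rates over a series
#'
#' Ordinary least-squares slopes of volume (and of log-volume) against
#' time; the three-point analogues of the pairwise rates.
#'
#' @param obs Data frame with `time_months`, `volume_mm3` (>= 3 rows), or
#'   `NULL` when `times`/`volumes` are given.
#' @param times,volumes Alternative bare-vector interface.
#' @return A named list with `nu_ls` (mm^3/month) and `lambda_ls`
#'   (1/month).
#' @export
ls_rates <- function(obs = NULL, times = NULL, volumes = NULL) {
  d <- .fit_obs(obs, times, volumes)
  if (nrow(d) < 3) stop_param("At least 3 observations are required.")
  t <- d$time_months
  ols_slope <- function(y) sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  list(nu_ls = ols_slope(d$volume_mm3),
       lambda_ls = ols_slope(log(d$volume_mm3)))
}

#' Modified Schwartz volume doubling time
#'
#' `VDT = ln2 / lambda`, assuming exponential growth. A negative rate
#' yields a negative (shrinkage) doubling time, passed through for
#' downstream handling; a zero rate yields `Inf`.
#'
#' @param lam Exponential growth rate, 1/month.
#' @return Doubling time in months.
#' @examples
#' vdt_schwartz(exp_rate(100, 200, 12)) # 12
#' @export
vdt_schwartz <- function(lam) {
  ifelse(lam == 0, Inf, log(2) / lam)
}

#' Scaling-law volume doubling time
#'
#' Time for the von Bertalanffy solution to double its baseline volume:
#' `VDT_beta = ((2 V0)^(1-beta) - V0^(1-beta)) / ((1-beta) * alpha)`,
#' with the limit `ln2 / alpha` at `beta = 1`. The formula is evaluated
#' in the cancellation-free form `V0^c * expm1(c * ln 2) / (c * alpha)`
#' (`c = 1 - beta`), and exponents within `1e-6` of 1 take the limit
#' directly so the doubling time is numerically continuous across the
#' exponential point.
#'
#' @param v0 Baseline volume (mm^3, positive).
#' @param alpha Growth coefficient.
#' @param beta Growth exponent.
#' @return Doubling time in months (`Inf` when `alpha = 0`; signed when
#'   the volume is shrinking).
#' @examples
#' vdt_beta(100, 10, 0) # 10 months: (200 - 100) / 10
#' @export
vdt_beta <- function(v0, alpha, beta) {
  if (any(v0 <= 0)) stop_domain("`v0` must be positive.")
  out <- numeric(length(v0))
  n <- max(length(v0), length(alpha), length(beta))
  v0 <- rep_len(v0, n); alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  cc <- 1 - beta
  exp_branch <- abs(cc) < 1.5e-6 # covers 1 +/- 1e-6 despite float rounding
  zero_alpha <- alpha == 0
  out <- ifelse(zero_alpha, Inf,
         ifelse(exp_branch, log(2) / alpha,
                v0^cc * expm1(cc * log(2)) / (cc * alpha)))
  out
}

#' Lesion mass
#'
#' Product of volume and mean attenuation; usually negative for lung
#' nodules since their mean HU is negative.
#'
#' @param volume Volume in mm^3 (positive).
#' @param hu Mean attenuation in Hounsfield Units.
#' @return Mass surrogate in mm^3 * HU.
#' @examples
#' lesion_mass(100, -146) # -14600
#' @export
lesion_mass <- function(volume, hu) {
  if (any(volume <= 0, na.rm = TRUE)) stop_domain("`volume` must be positive.")
  volume * hu
}

#' Compute the kinetic feature set for every nodule
#'
#' One row per nodule with all candidate discriminators: the fitted
#' `(alpha, beta)` and `vdt_beta`, the three pairwise linear and
#' exponential rates over the first three scans, their least-squares
#' analogues, both Schwartz-type doubling times (`vdt_exp_01` from the
#' first interval, `vdt_exp_ls` from the least-squares log-slope), and
#' the baseline volume, attenuation and mass. Missing attenuation makes
#' `hu0`/`mass0` `NA`, never zero.
#'
#' @param cohort A cohort tibble whose nodules passed
#'   [inclusion_filter()] (nodules that cannot be fitted get `NA` fit
#'   columns).
#' @param fit_method Passed to [fit_growth()].
#' @return A tibble with one row per nodule; columns `nodule_id`,
#'   `malignancy`, `morphology`, `beta`, `alpha`, `vdt_beta`, `nu_01`,
#'   `nu_02`, `nu_12`, `nu_ls`, `lambda_01`, `lambda_02`, `lambda_12`,
#'   `lambda_ls`, `vdt_exp_01`, `vdt_exp_ls`, `v0`, `hu0`, `mass0`.
#' @export
compute_features <- function(cohort, fit_method = c("exact3", "least_squares")) {
  fit_method <- match.arg(fit_method)
  cohort <- as_cohort(cohort, rebase = FALSE)
  fits <- fit_growth(cohort, method = fit_method)
  feat_one <- function(d) {
    d <- d[order(d$time_months), ][seq_len(3), ]
    t <- d$time_months - d$time_months[1]
    v <- d$volume_mm3
    hu0 <- d$attenuation_hu[1]
    ls <- ls_rates(times = t, volumes = v)
    tibble::tibble(
      nu_01 = linear_rate(v[1], v[2], t[2]),
      nu_02 = linear_rate(v[1], v[3], t[3]),
      nu_12 = linear_rate(v[2], v[3], t[3] - t[2]),
      nu_ls = ls$nu_ls,
      lambda_01 = exp_rate(v[1], v[2], t[2]),
      lambda_02 = exp_rate(v[1], v[3], t[3]),
      lambda_12 = exp_rate(v[2], v[3], t[3] - t[2]),
      lambda_ls = ls$lambda_ls,
      vdt_exp_01 = vdt_schwartz(lambda_01),
      vdt_exp_ls = vdt_schwartz(lambda_ls),
      v0 = v[1],
      hu0 = if (is.na(hu0)) NA_real_ else hu0,
      mass0 = if (is.na(hu0)) NA_real_ else lesion_mass(v[1], hu0)
    )
  }
  n_scans <- dplyr::count(cohort, .data$nodule_id)
  if (any(n_scans$n < 3)) {
    stop_param(sprintf(
      "Nodule '%s' has fewer than 3 scans; run inclusion_filter() first.",
      n_scans$nodule_id[n_scans$n < 3][1]))
  }
  feats <- cohort |>
    dplyr::group_by(.data$nodule_id, .data$malignancy, .data$morphology) |>
    dplyr::group_modify(~ feat_one(.x)) |>
    dplyr::ungroup()
  out <- dplyr::left_join(
    dplyr::select(fits, "nodule_id", "malignancy", "morphology",
                  "alpha", "beta"),
    feats, by = c("nodule_id", "malignancy", "morphology"))
  out$vdt_beta <- ifelse(is.na(out$beta), NA_real_,
                         vdt_beta(out$v0, out$alpha, out$beta))
  dplyr::select(out, "nodule_id", "malignancy", "morphology",
                "beta", "alpha", "vdt_beta",
                "nu_01", "nu_02", "nu_12", "nu_ls",
                "lambda_01", "lambda_02", "lambda_12", "lambda_ls",
                "vdt_exp_01", "vdt_exp_ls", "v0", "hu0", "mass0")
}

#' Write a feature matrix as CSV
#'
#' One row per nodule, columns named as in [compute_features()], missing
#' values as empty cells.
#'
#' @param features Tibble from [compute_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, na = "", progress = FALSE)
  invisible(path)
}
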