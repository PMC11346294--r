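#' The von Bertalanffy scaling law
#'
#' Nodule growth is modelled by the power-law ODE `dV/dt = alpha * V^beta`.
#' Its analytic solution is
#' `V(t)^(1-beta) = V0^(1-beta) + (1-beta) * alpha * t` for `beta != 1`,
#' and `V(t) = V0 * exp(alpha * t)` for `beta = 1`. The dimensionless
#' exponent `beta` indexes the growth pattern (see [classify_growth()]);
#' for `beta > 1` the solution blows up at the finite time
#' `t* = V0^(1-beta) / ((beta - 1) * alpha)`.
#'
#' @name vb_model
NULL

# threshold below which |1 - beta| is treated as the exponential branch,
# avoiding catastrophic cancellation in the power-law form
.beta_one_tol <- 1e-8

#' Forward-solve the von Bertalanffy growth law
#'
#' @param v0 Baseline volume in mm^3 (positive).
#' @param alpha Growth coefficient, units mm^(3(1-beta))/month.
#' @param beta Dimensionless growth exponent.
#' @param times Months since baseline (non-negative). For `beta > 1` all
#'   times must lie strictly below the blow-up time `t*`.
#' @return Volumes in mm^3 at `times`; `V(0) = v0` exactly.
#' @examples
#' vb_solve_forward(100, 10, 0, c(0, 12, 24))   # linear: 100, 220, 340
#' vb_solve_forward(100, 0.1, 1, c(0, 12))      # exponential
#' @export
vb_solve_forward <- function(v0, alpha, beta, times) {
  if (!is.numeric(v0) || length(v0) != 1 || v0 <= 0) {
    stop_domain("`v0` must be a single positive volume.")
  }
  if (any(times < 0)) stop_domain("`times` must be non-negative.")
  if (!is.finite(alpha) || !is.finite(beta)) {
    stop_domain("`alpha` and `beta` must be finite.")
  }
  if (abs(1 - beta) < .beta_one_tol) {
    return(v0 * exp(alpha * times))
  }
  cc <- 1 - beta
  if (beta > 1 && alpha > 0) {
    t_star <- v0^cc / ((beta - 1) * alpha)
    if (any(times >= t_star)) {
      stop_domain(sprintf(
        "Requested time at or beyond the blow-up time t* = %.6g months.",
        t_star))
    }
  }
  base <- v0^cc + cc * alpha * times
  if (any(base <= 0)) {
    stop_domain("Solution undefined: V0^(1-beta) + (1-beta)*alpha*t <= 0.")
  }
  out <- base^(1 / cc)
  out[times == 0] <- v0 # exact at baseline, no power round trip
  out
}

#' Growth-pattern categories of the growth exponent
#'
#' Bins the fitted exponent into the five growth patterns. The bins are
#' upper-inclusive: decelerated `beta <= -0.1`; linear
#' `-0.1 < beta <= 0.1`; subexponential `0.1 < beta <= 0.9`; exponential
#' `0.9 < beta <= 1.1`; accelerated `beta > 1.1`.
#'
#' @param beta Numeric vector of finite growth exponents.
#' @return Factor with levels `decelerated`, `linear`, `subexponential`,
#'   `exponential`, `accelerated`.
#' @examples
#' classify_growth(c(-0.1, 0, 0.77, 1.1, 1.1000001))
#' @export
classify_growth <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    stop_domain("`beta` must be finite numeric.")
  }
  cut(beta,
      breaks = c(-Inf, -0.1, 0.1, 0.9, 1.1, Inf),
      labels = growth_categories(),
      right = TRUE)
}

#' @rdname classify_growth
#' @export
growth_categories <- function() {
  c("decelerated", "linear", "subexponential", "exponential", "accelerated")
}

new_vb_fit <- function(alpha, beta, method, residual, converged, data) {
  structure(
    list(alpha = alpha, beta = beta, method = method, residual = residual,
         category = as.character(classify_growth(beta)),
         converged = converged, n_obs = nrow(data), data = data),
    class = "vb_fit")
}

#' @export
print.vb_fit <- function(x, ...) {
  cat(sprintf(
    "von Bertalanffy fit (%s, n = %d)\n  alpha = %.6g  beta = %.6g  [%s]\n  RMS log-volume residual = %.3g  converged = %s\n",
    x$method, x$n_obs, x$alpha, x$beta, x$category, x$residual, x$converged))
  invisible(x)
}

# observations: data frame with time_months, volume_mm3 (optionally a bare
# numeric pair of vectors via times=/volumes=)
.fit_obs <- function(obs, times = NULL, volumes = NULL) {
  if (!is.null(obs)) {
    stopifnot(is.data.frame(obs))
    times <- obs$time_months
    volumes <- obs$volume_mm3
  }
  ord <- order(times)
  tibble::tibble(time_months = times[ord] - times[ord][1],
                 volume_mm3 = volumes[ord])
}

#' Exact three-point fit of the growth law
#'
#' Solves for `(alpha, beta)` such that the analytic solution passes
#' through three strictly increasing volumes exactly. The problem reduces
#' to a one-dimensional root-find in `c = 1 - beta` on
#' `f(c) = expm1(c*a1) / expm1(c*a2) - t1/t2`, with `a_i = log(V_i/V0)`
#' and times re-based to `t0 = 0`; `f` is strictly decreasing with range
#' `(0, 1) - t1/t2`, so the root is unique. The `beta = 1` branch
#' (`c -> 0`) is the limit `a1/a2 = t1/t2` and is handled through the
#' log-form closed expression.
#'
#' @param obs Data frame with columns `time_months`, `volume_mm3`
#'   (exactly 3 rows), or `NULL` when `times`/`volumes` are given.
#' @param times,volumes Alternative bare-vector interface (length 3).
#' @param beta_range Search bracket for the exponent; a root at the
#'   bracket edge raises a convergence error rather than clamping.
#' @return A `vb_fit` object (residual 0 up to solver tolerance).
#' @examples
#' vb_fit_exact3(times = c(0, 12, 24), volumes = c(100, 220, 340)) # beta = 0
#' @export
vb_fit_exact3 <- function(obs = NULL, times = NULL, volumes = NULL,
                          beta_range = c(-10, 10)) {
  d <- .fit_obs(obs, times, volumes)
  if (nrow(d) != 3) stop_param("Exactly 3 observations are required.")
  t1 <- d$time_months[2]; t2 <- d$time_months[3]
  v0 <- d$volume_mm3[1]; v1 <- d$volume_mm3[2]; v2 <- d$volume_mm3[3]
  if (!(t2 > t1 && t1 > 0)) stop_param("Times must be strictly increasing.")
  if (!(v2 > v1 && v1 > v0)) {
    stop_domain("Volumes must be strictly increasing for the 3-point fit.")
  }
  a1 <- log(v1 / v0); a2 <- log(v2 / v0)
  r <- t1 / t2
  g <- function(cc) {
    if (abs(cc) < 1e-12) a1 / a2 else expm1(cc * a1) / expm1(cc * a2)
  }
  lo <- 1 - beta_range[2]; hi <- 1 - beta_range[1]
  f_lo <- g(lo) - r; f_hi <- g(hi) - r
  if (f_lo == 0 || f_hi == 0 || sign(f_lo) == sign(f_hi)) {
    stop_convergence(sprintf(
      "Growth exponent root not bracketed in beta range [%g, %g].",
      beta_range[1], beta_range[2]))
  }
  root <- uniroot(function(cc) g(cc) - r, lower = lo, upper = hi,
                  tol = .Machine$double.eps^0.75, maxiter = 2000)
  cc <- root$root
  if (abs(cc) < .beta_one_tol) {
    beta <- 1
    alpha <- a1 / t1
  } else {
    beta <- 1 - cc
    alpha <- (v1^cc - v0^cc) / (cc * t1)
  }
  pred <- vb_solve_forward(v0, alpha, beta, d$time_months)
  residual <- sqrt(mean((log(d$volume_mm3) - log(pred))^2))
  new_vb_fit(alpha, beta, "exact3", residual, TRUE, d)
}

#' Least-squares fit of the growth law for longer series
#'
#' Minimizes the sum of squared log-volume residuals of the analytic
#' solution over `(alpha, beta)` with `V0` fixed at the baseline volume
#' (a multiplicative error model, consistent with the sensitivity
#' analysis). Initialized from the exact three-point fit on the first,
#' middle and last observations; a three-point series returns the exact
#' fit directly.
#'
#' @inheritParams vb_fit_exact3
#' @param obs Data frame with `>= 3` rows.
#' @return A `vb_fit` object; non-convergence is reported in the
#'   `converged` flag, never silently.
#' @export
vb_fit_ls <- function(obs = NULL, times = NULL, volumes = NULL,
                      beta_range = c(-10, 10)) {
  d <- .fit_obs(obs, times, volumes)
  if (nrow(d) < 3) stop_param("At least 3 observations are required.")
  if (nrow(d) == 3) {
    fit <- vb_fit_exact3(d, beta_range = beta_range)
    fit$method <- "least_squares"
    return(fit)
  }
  n <- nrow(d)
  mid <- ceiling(n / 2)
  init <- tryCatch(
    vb_fit_exact3(d[c(1, mid, n), ], beta_range = beta_range),
    error = function(e) NULL)
  lam <- (log(d$volume_mm3[n]) - log(d$volume_mm3[1])) / d$time_months[n]
  start <- if (is.null(init)) c(alpha = lam, beta = 1) else
    c(alpha = init$alpha, beta = init$beta)
  v0 <- d$volume_mm3[1]
  logv <- log(d$volume_mm3)
  objective <- function(par) {
    pred <- tryCatch(
      vb_solve_forward(v0, par[1], par[2], d$time_months),
      error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      return(1e10 * (1 + sum(par^2)))
    }
    sum((logv - log(pred))^2)
  }
  ctrl <- list(rel.tol = 1e-15, x.tol = 1e-12,
               eval.max = 5000, iter.max = 2000)
  opt <- nlminb(start, objective,
                lower = c(-Inf, beta_range[1]),
                upper = c(Inf, beta_range[2]), control = ctrl)
  conv_ok <- opt$convergence == 0
  if (!conv_ok) {
    # nlminb reports "false convergence" when started at (or driven to)
    # the optimum; accept the solution if a restart cannot improve it
    opt2 <- nlminb(opt$par, objective,
                   lower = c(-Inf, beta_range[1]),
                   upper = c(Inf, beta_range[2]), control = ctrl)
    if (opt2$objective < opt$objective) opt <- opt2
    conv_ok <- opt2$convergence == 0 ||
      opt2$objective >= opt$objective - 1e-12 * (1 + abs(opt$objective))
  }
  alpha <- unname(opt$par[1]); beta <- unname(opt$par[2])
  converged <- conv_ok &&
    beta > beta_range[1] + 1e-6 && beta < beta_range[2] - 1e-6
  pred <- tryCatch(vb_solve_forward(v0, alpha, beta, d$time_months),
                   error = function(e) rep(NA_real_, n))
  residual <- sqrt(mean((logv - log(pred))^2))
  new_vb_fit(alpha, beta, "least_squares", residual, converged, d)
}

#' Fit the growth law to every nodule of a cohort
#'
#' Fits each retained nodule with the exact three-point solver on its
#' first three scans (the default, matching the model's `V0, V1, V2`
#' parameterisation) or with the least-squares solver on all scans.
#'
#' @param cohort A cohort tibble (pass it through [inclusion_filter()]
#'   first; non-fittable nodules yield an `NA` row with `converged =
#'   FALSE` rather than an error).
#' @param method `"exact3"` (first three scans) or `"least_squares"`
#'   (all scans).
#' @return A tibble with one row per nodule: `nodule_id`, `malignancy`,
#'   `morphology`, `alpha`, `beta`, `method`, `residual`, `category`,
#'   `converged`.
#' @export
fit_growth <- function(cohort, method = c("exact3", "least_squares")) {
  method <- match.arg(method)
  cohort <- as_cohort(cohort, rebase = FALSE)
  fit_one <- function(d) {
    fit <- tryCatch({
      if (method == "exact3") vb_fit_exact3(d[seq_len(3), ]) else vb_fit_ls(d)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      tibble::tibble(alpha = NA_real_, beta = NA_real_, method = method,
                     residual = NA_real_, category = NA_character_,
                     converged = FALSE)
    } else {
      tibble::tibble(alpha = fit$alpha, beta = fit$beta, method = fit$method,
                     residual = fit$residual, category = fit$category,
                     converged = fit$converged)
    }
  }
  cohort |>
    dplyr::group_by(.data$nodule_id, .data$malignancy, .data$morphology) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup()
}

#' Tabulate growth categories by malignancy
#'
#' @param fits A tibble from [fit_growth()].
#' @return A tibble with one row per growth category and one count column
#'   per malignancy group (categories with zero counts included).
#' @export
category_table <- function(fits) {
  fits <- dplyr::filter(fits, !is.na(.data$category))
  fits$category <- factor(fits$category, levels = growth_categories())
  fits |>
    dplyr::count(.data$malignancy, .data$category, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "malignancy", values_from = "n",
                       values_fill = 0L)
}

#' @method tidy vb_fit
#' @export
tidy.vb_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha, x$beta))
}

#' @method glance vb_fit
#' @export
glance.vb_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, category = x$category,
                 method = x$method, residual = x$residual,
                 converged = x$converged, n_obs = x$n_obs)
}
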