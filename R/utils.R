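#' Convert between days and months
#'
#' Scan intervals are stored in months; some sources report days. The
#' conversion uses the mean Gregorian month of 30.4375 days.
#'
#' @param x Numeric vector of durations.
#' @return Numeric vector in the target unit.
#' @examples
#' days_to_months(365.25) # 12
#' @export
days_to_months <- function(x) x / 30.4375

#' @rdname days_to_months
#' @export
months_to_days <- function(x) x * 30.4375

# Asymmetric triangular sampler by inverse CDF. Used for scan-schedule
# jitter; (min, mode, max) need not be symmetric.
rtri <- function(n, min, mode, max) {
  stopifnot(min < mode, mode < max)
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
    min + sqrt(u * (max - min) * (mode - min)),
    max - sqrt((1 - u) * (max - min) * (max - mode))
  )
}

stop_domain <- function(msg, ...) {
  abort(msg, class = "nodulegrowth_domain_error", ...)
}

stop_param <- function(msg, ...) {
  abort(msg, class = "nodulegrowth_parameter_error", ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "nodulegrowth_validation_error", ...)
}

stop_convergence <- function(msg, ...) {
  abort(msg, class = "nodulegrowth_convergence_error", ...)
}

# Seed handling: set the RNG state only when a seed is supplied, so that
# callers embedded in a larger seeded computation can pass seed = NULL.
set_seed_if_given <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      stop_param("`seed` must be a single finite number or NULL.")
    }
    set.seed(as.integer(seed))
  }
  invisible(seed)
}
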