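# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms (brute force, numeric ODE
# integration, grid search) from the code paths they validate.

# Tie-aware AUC by brute-force concordant-pair counting:
# P(score_mal > score_ben) + 0.5 * P(equal).
auc_bruteforce <- function(scores, labels) {
  s_mal <- scores[labels == "malignant"]
  s_ben <- scores[labels == "benign"]
  cmp <- outer(s_mal, s_ben, function(m, b) (m > b) + 0.5 * (m == b))
  mean(cmp)
}

# Numeric integration of dV/dt = alpha * V^beta with deSolve.
ode_solve_vb <- function(v0, alpha, beta, times) {
  rhs <- function(t, y, parms) list(parms$alpha * y^parms$beta)
  out <- deSolve::lsoda(c(V = v0), times = sort(unique(c(0, times))),
                        func = rhs, parms = list(alpha = alpha, beta = beta),
                        rtol = 1e-12, atol = 1e-12)
  out[match(times, out[, "time"]), "V"]
}

# Time at which the ODE solution reaches 2 * v0, via root-finding during
# integration.
ode_time_to_double <- function(v0, alpha, beta, t_max = 1e4) {
  rhs <- function(t, y, parms) list(parms$alpha * y^parms$beta)
  root <- function(t, y, parms) y - 2 * v0
  out <- deSolve::lsodar(c(V = v0), times = c(0, t_max), func = rhs,
                         parms = list(alpha = alpha, beta = beta),
                         rootfunc = root, rtol = 1e-11, atol = 1e-11)
  tr <- attributes(out)$troot
  if (length(tr) == 0) NA_real_ else tr[1]
}

# Grid-search-and-refine oracle for the exact three-point fit: minimize
# the three-point consistency residual over a beta grid, then refine by
# golden-section around the best cell.
exact3_gridsearch <- function(times, volumes, beta_lim = c(-5, 5),
                              step = 1e-4) {
  t1 <- times[2] - times[1]; t2 <- times[3] - times[1]
  a1 <- log(volumes[2] / volumes[1]); a2 <- log(volumes[3] / volumes[1])
  resid <- function(beta) {
    cc <- 1 - beta
    g <- if (abs(cc) < 1e-12) a1 / a2 else expm1(cc * a1) / expm1(cc * a2)
    abs(g - t1 / t2)
  }
  grid <- seq(beta_lim[1], beta_lim[2], by = step)
  vals <- vapply(grid, resid, numeric(1))
  b0 <- grid[which.min(vals)]
  opt <- optimize(resid, c(b0 - step, b0 + step), tol = 1e-12)
  beta <- opt$minimum
  cc <- 1 - beta
  alpha <- if (abs(cc) < 1e-8) a1 / t1 else
    (volumes[2]^cc - volumes[1]^cc) / (cc * t1)
  c(alpha = alpha, beta = beta)
}

# Random strictly increasing three-scan series with non-degenerate
# increments (log-increments in [0.1, 1.5], so the implied exponent is
# finite and bracketable).
random_increasing_triple <- function() {
  t1 <- runif(1, 3, 18)
  t2 <- t1 + runif(1, 3, 18)
  v0 <- exp(runif(1, log(30), log(600)))
  v1 <- v0 * exp(runif(1, 0.1, 1.5))
  v2 <- v1 * exp(runif(1, 0.1, 1.5))
  list(times = c(0, t1, t2), volumes = c(v0, v1, v2))
}

# Small hand-built cohort data frame (2 nodules x 3 scans).
toy_cohort <- function() {
  tibble::tibble(
    nodule_id = rep(c("a", "b"), each = 3),
    malignancy = rep(c("benign", "malignant"), each = 3),
    morphology = rep(c("solid", "part_solid"), each = 3),
    time_months = rep(c(0, 12, 24), 2),
    volume_mm3 = c(100, 120, 150, 100, 220, 340),
    attenuation_hu = c(-146, -156, -131, -314, -291, -233))
}
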