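test_that("forward solution reproduces the closed forms", {
  # exponential branch
  expect_equal(vb_solve_forward(100, 0.1, 1, c(0, 12, 24)),
               100 * exp(c(0, 1.2, 2.4)))
  # linear branch
  expect_equal(vb_solve_forward(100, 10, 0, c(0, 12, 24)), c(100, 220, 340))
  # V(0) = v0 exactly for any exponent
  for (beta in c(-2, 0.5, 1, 1.7)) {
    expect_identical(vb_solve_forward(100, 0.01, beta, 0), 100)
  }
})

test_that("forward solution matches numeric ODE integration", {
  cases <- list(c(100, 0.00702, 1.4), c(150, 0.003, 1.4),
                c(100, 2, 0.5), c(200, 0.05, 1), c(80, 30, -0.5))
  for (cs in cases) {
    times <- c(6, 12, 24)
    expect_equal(vb_solve_forward(cs[1], cs[2], cs[3], times),
                 unname(ode_solve_vb(cs[1], cs[2], cs[3], times)),
                 tolerance = 1e-6)
  }
  # the accelerated reference trajectory passes close to 181.8 at one year
  expect_equal(vb_solve_forward(100, 0.00702, 1.4, 12), 181.8,
               tolerance = 1e-3)
})

test_that("forward solution refuses the blow-up domain", {
  # t* = V0^(1-beta) / ((beta-1) alpha)
  v0 <- 100; alpha <- 0.0075; beta <- 1.5
  t_star <- v0^(1 - beta) / ((beta - 1) * alpha)
  expect_error(vb_solve_forward(v0, alpha, beta, t_star),
               "blow-up", class = "nodulegrowth_domain_error")
  expect_silent(vb_solve_forward(v0, alpha, beta, t_star * 0.99))
  # shrinking sub-linear solution hitting zero volume
  expect_error(vb_solve_forward(100, -30, 0, 10),
               class = "nodulegrowth_domain_error")
})

test_that("exact three-point fit recovers closed-form identities", {
  fit_exp <- vb_fit_exact3(times = c(0, 12, 24),
                           volumes = 100 * exp(0.1 * c(0, 12, 24)))
  expect_equal(fit_exp$beta, 1, tolerance = 1e-9)
  expect_equal(fit_exp$alpha, 0.1, tolerance = 1e-9)

  fit_lin <- vb_fit_exact3(times = c(0, 12, 24), volumes = c(100, 220, 340))
  expect_equal(fit_lin$beta, 0, tolerance = 1e-9)
  expect_equal(fit_lin$alpha, 10, tolerance = 1e-9)
  expect_equal(fit_lin$category, "linear")
  expect_lt(fit_lin$residual, 1e-10)
})

test_that("exact fit agrees with the grid-search oracle", {
  v <- vb_solve_forward(150, 0.003, 1.4, c(0, 12, 24))
  fit <- vb_fit_exact3(times = c(0, 12, 24), volumes = v)
  expect_equal(fit$beta, 1.4, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.003, tolerance = 1e-6)
  oracle <- exact3_gridsearch(c(0, 12, 24), v)
  expect_equal(fit$beta, unname(oracle["beta"]), tolerance = 1e-6)
  expect_equal(fit$alpha, unname(oracle["alpha"]), tolerance = 1e-6)
})

test_that("exact fit rejects bad inputs loudly", {
  expect_error(vb_fit_exact3(times = c(0, 12, 24), volumes = c(100, 95, 120)),
               class = "nodulegrowth_domain_error")
  expect_error(vb_fit_exact3(times = c(0, 12), volumes = c(100, 200)),
               class = "nodulegrowth_parameter_error")
  # an exponent outside a narrow bracket raises, never clamps
  v <- vb_solve_forward(100, 2e-4, 2, c(0, 12, 18))
  expect_error(vb_fit_exact3(times = c(0, 12, 18), volumes = v,
                             beta_range = c(-1, 1)),
               class = "nodulegrowth_convergence_error")
})

test_that("forward-solve / refit round trip holds across the exponent grid", {
  for (beta in seq(-3, 3, by = 0.1)) {
    v0 <- 120
    # pick alpha so the 24-month trajectory doubles: valid for every beta
    alpha <- if (abs(1 - beta) < 1e-12) log(2) / 24 else
      ((2 * v0)^(1 - beta) - v0^(1 - beta)) / ((1 - beta) * 24)
    v <- vb_solve_forward(v0, alpha, beta, c(0, 12, 24))
    fit <- vb_fit_exact3(times = c(0, 12, 24), volumes = v)
    expect_equal(fit$beta, beta, tolerance = 1e-6)
    expect_equal(fit$alpha, alpha, tolerance = 1e-6 * max(1, abs(alpha)))
  }
})

test_that("the three-point root is unique and bracketing always succeeds", {
  set.seed(42)
  for (i in seq_len(1000)) {
    tr <- random_increasing_triple()
    fit <- vb_fit_exact3(times = tr$times, volumes = tr$volumes,
                         beta_range = c(-50, 50))
    expect_true(fit$converged)
    # the fit interpolates all three points (residual is solver noise)
    expect_lt(fit$residual, 1e-6)
    # for accelerated fits the observed times must precede blow-up
    if (fit$beta > 1 && fit$alpha > 0) {
      t_star <- tr$volumes[1]^(1 - fit$beta) / ((fit$beta - 1) * fit$alpha)
      expect_gt(t_star, max(tr$times))
    }
  }
})

test_that("growth categories partition the real line with printed bounds", {
  expect_equal(as.character(classify_growth(c(-0.1, 0, 0.77, 1.1, 1.1000001))),
               c("decelerated", "linear", "subexponential", "exponential",
                 "accelerated"))
  expect_equal(as.character(classify_growth(c(-5, 0.1, 0.9, 2.4))),
               c("decelerated", "linear", "subexponential", "accelerated"))
  # every finite exponent maps to exactly one category
  set.seed(1)
  b <- runif(500, -10, 10)
  expect_false(anyNA(classify_growth(b)))
  expect_error(classify_growth(Inf), class = "nodulegrowth_domain_error")
})

test_that("least-squares fit reduces to the exact fit at three points", {
  v <- vb_solve_forward(100, 2, 0.5, c(0, 10, 25))
  f3 <- vb_fit_exact3(times = c(0, 10, 25), volumes = v)
  fls <- vb_fit_ls(times = c(0, 10, 25), volumes = v)
  expect_equal(fls$beta, f3$beta, tolerance = 1e-12)
  expect_equal(fls$alpha, f3$alpha, tolerance = 1e-12)
  expect_equal(fls$method, "least_squares")
})

test_that("least-squares fit recovers noiseless five-point trajectories", {
  times <- c(0, 6, 12, 18, 24)
  v <- vb_solve_forward(100, 2, 0.5, times)
  fit <- vb_fit_ls(times = times, volumes = v)
  expect_true(fit$converged)
  expect_equal(fit$beta, 0.5, tolerance = 1e-6)
  expect_equal(fit$alpha, 2, tolerance = 1e-6)
})

test_that("least-squares exponent is unbiased under mild volumetry noise", {
  times <- c(0, 6, 12, 18, 24)
  truth <- vb_solve_forward(100, 2, 0.5, times)
  set.seed(7)
  betas <- vapply(seq_len(500), function(i) {
    v <- truth * (1 + runif(5, -0.01, 0.01))
    fit <- tryCatch(vb_fit_ls(times = times, volumes = v),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$beta
  }, numeric(1))
  expect_lt(abs(median(betas, na.rm = TRUE) - 0.5), 0.1)
})

test_that("cohort-level fitting returns a tidy per-nodule table", {
  co <- generate_fixture("tiny")
  res <- inclusion_filter(co)
  fits <- fit_growth(res$retained)
  expect_equal(nrow(fits), 5)
  expect_true(all(fits$converged))
  expect_setequal(fits$category, growth_categories())
  tab <- category_table(fits)
  expect_equal(sum(tab$benign) + sum(tab$malignant), 5)

  # tidy/glance accessors on a single fit
  f <- vb_fit_exact3(times = c(0, 12, 24), volumes = c(100, 220, 340))
  expect_equal(tidy(f)$estimate, c(10, 0), tolerance = 1e-9)
  expect_equal(glance(f)$category, "linear")
})
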