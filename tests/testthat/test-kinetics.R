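test_that("pairwise rates compute their defining quotients", {
  expect_equal(linear_rate(100, 340, 24), 10)
  expect_equal(linear_rate(100, 100, 12), 0)
  # interval medians of a screening schedule, hand arithmetic
  expect_equal(linear_rate(103.5, 179.3, 12.2), 75.8 / 12.2)
  expect_equal(linear_rate(103.5, 179.3, 12.2), 6.213, tolerance = 1e-3)
  expect_error(linear_rate(100, 200, 0), class = "nodulegrowth_domain_error")

  expect_equal(exp_rate(100, 200, 12), log(2) / 12)
  expect_equal(exp_rate(100, 100, 12), 0)
  expect_equal(exp_rate(100, 100 * exp(1), 1), 1)
  expect_error(exp_rate(-1, 100, 12), class = "nodulegrowth_domain_error")
})

test_that("least-squares rates match closed-form OLS on three points", {
  ls <- ls_rates(times = c(0, 12, 24), volumes = c(100, 220, 340))
  expect_equal(ls$nu_ls, 10)
  ls2 <- ls_rates(times = c(0, 12, 24), volumes = 100 * exp(0.1 * c(0, 12, 24)))
  expect_equal(ls2$lambda_ls, 0.1)
  # non-collinear: OLS slope of (100, 150, 340) at 0/12/24 is 10
  ls3 <- ls_rates(times = c(0, 12, 24), volumes = c(100, 150, 340))
  expect_equal(ls3$nu_ls, 10)
  expect_error(ls_rates(times = c(0, 12), volumes = c(1, 2)),
               class = "nodulegrowth_parameter_error")
})

test_that("Schwartz VDT inverts the exponential rate", {
  expect_equal(vdt_schwartz(exp_rate(100, 200, 12)), 12)
  expect_equal(vdt_schwartz(log(2)), 1)
  expect_equal(vdt_schwartz(exp_rate(103.5, 179.3, 12.2)),
               log(2) * 12.2 / log(179.3 / 103.5))
  expect_equal(vdt_schwartz(exp_rate(103.5, 179.3, 12.2)), 15.39,
               tolerance = 1e-3)
  expect_identical(vdt_schwartz(0), Inf)
  expect_lt(vdt_schwartz(-0.05), 0) # shrinkage passes through signed
  # strictly decreasing in the rate
  lam <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(vdt_schwartz(lam)) < 0))
})

test_that("scaling-law VDT reduces to closed forms and is continuous at 1", {
  expect_equal(vdt_beta(100, 10, 0), 10)  # (2V0 - V0) / alpha
  alpha <- 0.05
  expect_equal(vdt_beta(100, alpha, 1), log(2) / alpha)
  expect_equal(vdt_beta(100, alpha, 1 + 1e-6), log(2) / alpha,
               tolerance = 1e-5)
  expect_equal(vdt_beta(100, alpha, 1 - 1e-6), log(2) / alpha,
               tolerance = 1e-5)
  expect_identical(vdt_beta(100, 0, 0.5), Inf)
  expect_error(vdt_beta(-1, 1, 0), class = "nodulegrowth_domain_error")
})

test_that("scaling-law VDT equals the ODE time-to-double", {
  a_ref <- ((400)^(-0.4) - 100^(-0.4)) / (-0.4 * 24)
  expect_equal(vdt_beta(100, a_ref, 1.4),
               ode_time_to_double(100, a_ref, 1.4), tolerance = 1e-6)
  set.seed(11)
  for (i in seq_len(25)) {
    v0 <- runif(1, 50, 500)
    beta <- runif(1, -2, 2.4)
    fc <- runif(1, 1.5, 4)
    alpha <- if (abs(1 - beta) < 1e-12) log(fc) / 24 else
      ((fc * v0)^(1 - beta) - v0^(1 - beta)) / ((1 - beta) * 24)
    expect_equal(vdt_beta(v0, alpha, beta), ode_time_to_double(v0, alpha, beta),
                 tolerance = 1e-6)
  }
})

test_that("lesion mass is the literal volume-attenuation product", {
  expect_equal(lesion_mass(100, -146), -14600)
  expect_equal(lesion_mass(100, 0), 0)
  expect_equal(lesion_mass(179.3, -314), -56300.2)
  expect_error(lesion_mass(0, -100), class = "nodulegrowth_domain_error")
})

test_that("feature extraction is internally consistent on exact series", {
  # exact exponential: all rate estimators agree, VDT_exp = VDT_beta
  co <- tibble::tibble(
    nodule_id = "e", malignancy = "malignant", morphology = "solid",
    time_months = c(0, 12, 24),
    volume_mm3 = 100 * exp(0.1 * c(0, 12, 24)),
    attenuation_hu = c(-300, -280, -250))
  ft <- compute_features(co)
  lam <- c(ft$lambda_01, ft$lambda_02, ft$lambda_12, ft$lambda_ls)
  expect_equal(lam, rep(0.1, 4), tolerance = 1e-9)
  expect_equal(ft$vdt_exp_01, ft$vdt_beta, tolerance = 1e-9)
  expect_equal(ft$beta, 1, tolerance = 1e-9)

  # exact linear: all linear-rate estimators agree and beta fits to 0
  co2 <- dplyr::mutate(co, volume_mm3 = c(100, 220, 340))
  ft2 <- compute_features(co2)
  expect_equal(c(ft2$nu_01, ft2$nu_02, ft2$nu_12, ft2$nu_ls), rep(10, 4))
  expect_equal(ft2$beta, 0, tolerance = 1e-9)
  expect_equal(ft2$v0, 100)
  expect_equal(ft2$hu0, -300)
  expect_equal(ft2$mass0, -30000)
})

test_that("accelerated growth doubles faster than the Schwartz projection", {
  a_ref <- ((400)^(-0.4) - 100^(-0.4)) / (-0.4 * 24)
  co <- tibble::tibble(
    nodule_id = "acc", malignancy = "malignant", morphology = "solid",
    time_months = c(0, 12, 24),
    volume_mm3 = vb_solve_forward(100, a_ref, 1.4, c(0, 12, 24)),
    attenuation_hu = NA_real_)
  ft <- compute_features(co)
  expect_lt(ft$vdt_beta, ft$vdt_exp_01)
  # missing attenuation makes HU features missing, never zero
  expect_true(is.na(ft$hu0) && is.na(ft$mass0))
})

test_that("rates scale with volume units while exponents do not", {
  set.seed(3)
  for (i in seq_len(20)) {
    tr <- random_increasing_triple()
    k <- runif(1, 0.5, 20)
    co <- tibble::tibble(
      nodule_id = "s", malignancy = "benign", morphology = "solid",
      time_months = tr$times, volume_mm3 = tr$volumes,
      attenuation_hu = NA_real_)
    f1 <- compute_features(co)
    f2 <- compute_features(dplyr::mutate(co, volume_mm3 = k * volume_mm3))
    expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
    expect_equal(f2$lambda_02, f1$lambda_02, tolerance = 1e-12)
    expect_equal(f2$vdt_exp_01, f1$vdt_exp_01, tolerance = 1e-12)
    expect_equal(f2$vdt_beta, f1$vdt_beta, tolerance = 1e-5)
    expect_equal(f2$nu_01, k * f1$nu_01, tolerance = 1e-12)
    expect_equal(f2$nu_ls, k * f1$nu_ls, tolerance = 1e-12)
  }
})

test_that("feature extraction demands three scans", {
  co <- toy_cohort()[1:2, ]
  expect_error(compute_features(co), "inclusion_filter",
               class = "nodulegrowth_parameter_error")
})
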