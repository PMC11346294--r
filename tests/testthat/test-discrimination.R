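.labels6 <- rep(c("benign", "malignant"), each = 3)

test_that("AUC matches brute-force pair counting, including ties", {
  ev <- roc_auc(c(1, 2, 3, 2, 3, 4), .labels6)
  expect_equal(ev$auc, 7 / 9, tolerance = 1e-12)
  expect_equal(ev$direction, "higher_is_malignant")
  # perfect separation and pure ties
  expect_equal(roc_auc(c(1, 2, 3, 4), rep(c("benign", "malignant"), each = 2))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 1, 2), rep(c("benign", "malignant"), each = 2))$auc, 0.5)
  set.seed(8)
  for (i in seq_len(200)) {
    n <- sample(4:30, 1)
    labels <- sample(rep(c("benign", "malignant"), length.out = n))
    scores <- sample(seq_len(8), n, replace = TRUE) + # heavy ties
      sample(c(0, 0.5), n, replace = TRUE)
    ev <- roc_auc(scores, labels)
    bf <- auc_bruteforce(scores, labels)
    expect_equal(ev$auc, max(bf, 1 - bf), tolerance = 1e-12)
  }
})

test_that("ROC geometry and direction bookkeeping are invariant", {
  set.seed(10)
  scores <- rnorm(40)
  labels <- sample(rep(c("benign", "malignant"), 20))
  ev <- roc_auc(scores, labels)
  # curve runs monotonically from (0,0) to (1,1)
  expect_equal(unlist(ev$roc_points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(ev$roc_points[nrow(ev$roc_points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(ev$roc_points$fpr) >= 0))
  expect_true(all(diff(ev$roc_points$tpr) >= 0))
  # AUC is invariant under strictly increasing transforms
  ev2 <- roc_auc(exp(scores), labels)
  expect_equal(ev2$auc, ev$auc, tolerance = 1e-12)
  # flipping labels flips the direction, not the AUC
  flipped <- ifelse(labels == "benign", "malignant", "benign")
  ev3 <- roc_auc(scores, flipped)
  expect_equal(ev3$auc, ev$auc, tolerance = 1e-12)
  expect_true(ev3$direction != ev$direction)
  expect_gte(ev$auc, 0.5)
  # single-class input is an error
  expect_error(roc_auc(scores, rep("benign", 40)),
               class = "nodulegrowth_validation_error")
})

test_that("Youden point is enumerated correctly with specificity tie-break", {
  ev <- roc_auc(c(1, 2, 3, 2, 3, 4), .labels6)
  op <- youden_operating_point(ev)
  # J ties at 1/3 across all non-trivial cuts; report the high-specificity one
  expect_equal(op$specificity, 1)
  expect_equal(op$sensitivity, 1 / 3, tolerance = 1e-12)
  # perfect separation reaches (1, 1)
  op2 <- youden_operating_point(
    roc_auc(c(1, 2, 3, 4), rep(c("benign", "malignant"), each = 2)))
  expect_equal(op2$sensitivity, 1)
  expect_equal(op2$specificity, 1)
  # identical distributions: J = 0 everywhere, a trivial cut is reported
  op3 <- youden_operating_point(
    roc_auc(c(1, 2, 1, 2), rep(c("benign", "malignant"), each = 2)))
  expect_equal(op3$sensitivity + op3$specificity - 1, 0, tolerance = 1e-12)
})

test_that("the feature table is evaluated in deterministic order", {
  co <- generate_cohort(cohort_spec(), seed = 5)
  ft <- compute_features(inclusion_filter(co)$retained)
  evals <- evaluate_features(ft)
  expect_equal(evals$feature, discrimination_features())
  expect_equal(nrow(evals), 16)
  expect_true(all(evals$auc >= 0.5))
  expect_true(all(evals$n_pos == 140 & evals$n_neg == 40))
  # growth separates better than baseline size under these effect sizes
  expect_gt(evals$auc[evals$feature == "nu_02"],
            evals$auc[evals$feature == "v0"])
  expect_equal(evals$direction[evals$feature == "nu_02"],
               "higher_is_malignant")
  expect_error(evaluate_features(ft, feature_cols = "not_a_feature"),
               class = "nodulegrowth_validation_error")
})

test_that("missing feature values are excluded pairwise with a count", {
  co <- generate_cohort(cohort_spec(), seed = 5)
  ft <- compute_features(inclusion_filter(co)$retained)
  ft$hu0[1:10] <- NA
  evals <- evaluate_features(ft)
  expect_equal(evals$n_missing[evals$feature == "hu0"], 10)
  expect_equal(evals$n_missing[evals$feature == "beta"], 0)
})

test_that("single-candidate score preserves the raw feature's AUC", {
  co <- generate_cohort(cohort_spec(), seed = 6)
  ft <- compute_features(inclusion_filter(co)$retained)
  mv <- multivariable_score(ft, "nu_02")
  raw <- roc_auc(ft$nu_02, ft$malignancy)
  expect_equal(mv$eval$auc, raw$auc, tolerance = 1e-12)
  expect_equal(mv$included, "nu_02")
})

test_that("backward elimination removes a pure-noise candidate", {
  co <- generate_cohort(cohort_spec(), seed = 12)
  ft <- compute_features(inclusion_filter(co)$retained)
  set.seed(99)
  ft$noise <- rnorm(nrow(ft))
  mv <- multivariable_score(ft, c("beta", "noise"))
  expect_equal(mv$included, "beta")
  expect_equal(mv$eliminated, "noise")
  expect_false(mv$penalized)
})

test_that("morphology indicators enter the model and separation is flagged", {
  co <- generate_cohort(cohort_spec(), seed = 13)
  ft <- compute_features(inclusion_filter(co)$retained)
  mv <- multivariable_score(ft, c("nu_02", "morphology"), p_stay = 1)
  expect_setequal(mv$included, c("nu_02", "morphology"))
  expect_true(any(grepl("morphology", names(mv$coefficients))))
  # linearly separable toy data: penalized fallback, AUC 1
  toy <- tibble::tibble(
    malignancy = rep(c("benign", "malignant"), each = 10),
    x = c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1)))
  mv2 <- multivariable_score(toy, "x")
  expect_true(mv2$penalized)
  expect_equal(mv2$eval$auc, 1)
})

test_that("rank-based group comparisons behave as expected", {
  # identical groups: no separation
  cmp0 <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(cmp0$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp0$p_value, 1, tolerance = 1e-9)
  # maximal rank separation at n = 3 + 3
  cmp1 <- compare_groups(c(1, 2, 3, 101, 102, 103), rep(c("a", "b"), each = 3))
  expect_lt(cmp1$p_value, 0.1)
  # three groups from one distribution: Holm-adjusted >= unadjusted
  set.seed(14)
  vals <- rnorm(30)
  grp <- rep(c("x", "y", "z"), each = 10)
  cmp2 <- compare_groups(vals, grp)
  raw <- suppressWarnings(
    pairwise.wilcox.test(vals, grp, p.adjust.method = "none"))$p.value
  raw <- raw[!is.na(raw)]
  expect_true(all(cmp2$pairwise$p_adj >= raw - 1e-12))
  expect_error(compare_groups(1:5, rep("a", 5)),
               class = "nodulegrowth_validation_error")
  expect_warning(compare_groups(c(1, 2, 3, 4), c("a", "a", "a", "b")),
                 "fewer than 2")
})

test_that("normality screening reports without gating anything", {
  set.seed(15)
  ft <- tibble::tibble(gauss = rnorm(100), skewed = exp(rnorm(100)))
  scr <- normality_screen(ft)
  expect_equal(scr$feature, c("gauss", "skewed"))
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
  expect_gt(scr$p_value[1], scr$p_value[2])
})
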