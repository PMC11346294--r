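#' Benign-versus-malignant discrimination
#'
#' ROC analysis of each candidate feature, Youden operating points, a
#' stepwise multivariable logistic score, and rank-based group
#' comparisons. ROC curves and AUCs are computed with \pkg{pROC}; the
#' AUC equals the tie-aware concordance probability
#' `P(score_mal > score_ben) + 0.5 * P(equal)`, with the scoring
#' direction chosen so that the reported AUC is always `>= 0.5` and
#' recorded explicitly.
#'
#' @name discrimination
NULL

.check_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("benign", "malignant"))
  if (length(bad) > 0) {
    stop_validation(sprintf("Labels must be benign/malignant; found: %s.",
                            paste(bad, collapse = ", ")))
  }
  labels
}

#' ROC curve and AUC for one feature
#'
#' @param scores Numeric per-nodule feature values; non-finite values are
#'   excluded pairwise with their count reported.
#' @param labels Character/factor vector of `"benign"` / `"malignant"`.
#' @return An object of class `roc_eval`: `auc`, `direction`
#'   (`"higher_is_malignant"` or `"lower_is_malignant"`), `roc_points`
#'   (tibble of `fpr`, `tpr` from `(0,0)` to `(1,1)`), `n_pos`, `n_neg`,
#'   `n_missing`.
#' @examples
#' roc_auc(c(1, 2, 3, 2, 3, 4),
#'         c("benign", "benign", "benign", "malignant", "malignant",
#'           "malignant"))$auc # 7/9
#' @export
roc_auc <- function(scores, labels) {
  labels <- .check_labels(labels)
  if (length(scores) != length(labels)) {
    stop_validation("`scores` and `labels` must have equal length.")
  }
  keep <- is.finite(scores)
  n_missing <- sum(!keep)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    stop_validation("Both classes must be present to evaluate a classifier.")
  }
  # fit in the higher-is-malignant direction, flip when that is the
  # weaker orientation, so the reported AUC is always >= 0.5
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c("benign", "malignant"), direction = "<",
                   quiet = TRUE)
  if (as.numeric(pROC::auc(roc)) < 0.5) {
    roc <- pROC::roc(response = labels, predictor = scores,
                     levels = c("benign", "malignant"), direction = ">",
                     quiet = TRUE)
  }
  ord <- order(1 - roc$specificities, roc$sensitivities)
  structure(
    list(auc = as.numeric(pROC::auc(roc)),
         direction = if (roc$direction == "<") "higher_is_malignant"
                     else "lower_is_malignant",
         roc_points = tibble::tibble(fpr = (1 - roc$specificities)[ord],
                                     tpr = roc$sensitivities[ord]),
         n_pos = sum(labels == "malignant"),
         n_neg = sum(labels == "benign"),
         n_missing = n_missing,
         .roc = roc),
    class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("ROC evaluation: AUC = %.3f (%s; %d malignant, %d benign)\n",
              x$auc, x$direction, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy roc_eval
#' @export
tidy.roc_eval <- function(x, ...) x$roc_points

#' @method glance roc_eval
#' @export
glance.roc_eval <- function(x, ...) {
  op <- youden_operating_point(x)
  tibble::tibble(auc = x$auc, direction = x$direction,
                 threshold = op$threshold, sensitivity = op$sensitivity,
                 specificity = op$specificity,
                 n_pos = x$n_pos, n_neg = x$n_neg, n_missing = x$n_missing)
}

#' Youden-index operating point
#'
#' The threshold maximizing `sensitivity + specificity - 1`; ties are
#' broken toward the higher-specificity point (screening economics
#' penalize false positives).
#'
#' @param eval A `roc_eval` from [roc_auc()].
#' @return A list with `threshold`, `sensitivity`, `specificity`.
#' @export
youden_operating_point <- function(eval) {
  stopifnot(inherits(eval, "roc_eval"))
  co <- pROC::coords(eval$.roc, "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[order(-co$specificity, -co$sensitivity), , drop = FALSE]
  list(threshold = co$threshold[1],
       sensitivity = co$sensitivity[1],
       specificity = co$specificity[1])
}

#' Canonical feature set evaluated for discrimination
#'
#' @return Character vector of the feature columns evaluated by default,
#'   in report order.
#' @export
discrimination_features <- function() {
  c("beta", "alpha", "vdt_beta",
    "nu_01", "nu_02", "nu_12", "nu_ls",
    "lambda_01", "lambda_02", "lambda_12", "lambda_ls",
    "vdt_exp_01", "vdt_exp_ls", "v0", "hu0", "mass0")
}

#' Evaluate every candidate feature as a classifier
#'
#' One ROC evaluation per feature column, with the Youden operating
#' point, in a deterministic order.
#'
#' @param features Tibble from [compute_features()] (or any tibble with a
#'   label column and numeric feature columns).
#' @param feature_cols Columns to evaluate; defaults to
#'   [discrimination_features()].
#' @param label_col Name of the benign/malignant label column.
#' @return A tibble with one row per feature: `feature`, `auc`,
#'   `direction`, `threshold`, `sensitivity`, `specificity`, `n_pos`,
#'   `n_neg`, `n_missing`, and a list-column `roc` of `roc_eval` objects.
#' @export
evaluate_features <- function(features, feature_cols = NULL,
                              label_col = "malignancy") {
  feature_cols <- feature_cols %||% discrimination_features()
  missing_cols <- setdiff(c(feature_cols, label_col), names(features))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("Missing feature column(s): %s.",
                            paste(missing_cols, collapse = ", ")))
  }
  labels <- .check_labels(features[[label_col]])
  rows <- purrr::map(feature_cols, function(fc) {
    ev <- roc_auc(features[[fc]], labels)
    op <- youden_operating_point(ev)
    tibble::tibble(feature = fc, auc = ev$auc, direction = ev$direction,
                   threshold = op$threshold, sensitivity = op$sensitivity,
                   specificity = op$specificity, n_pos = ev$n_pos,
                   n_neg = ev$n_neg, n_missing = ev$n_missing,
                   roc = list(ev))
  })
  purrr::list_rbind(rows)
}

# Logistic fit with optional ridge fallback under complete separation.
.fit_logistic <- function(df, terms, label_col) {
  fml <- stats::reformulate(terms, response = label_col)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # warnings are not a reliable separation signal; treat a vanishing
  # residual deviance (perfect in-sample fit) or IRLS non-convergence
  # as separation too
  separated <- separated || !fit$converged || fit$deviance < 1e-6
  if (!separated) {
    return(list(fit = fit, coef = coef(fit),
                scores = stats::predict(fit, type = "link"),
                p = summary(fit)$coefficients[, 4], separated = FALSE))
  }
  # weak L2 penalty keeps coefficients finite under perfect separation
  mm <- stats::model.matrix(fml, df)
  y <- as.numeric(df[[label_col]] == "malignant")
  lam <- 1e-3
  nll <- function(b) {
    eta <- drop(mm %*% b)
    sum(log1p(exp(eta))) - sum(y * eta) + 0.5 * lam * sum(b[-1]^2)
  }
  opt <- optim(rep(0, ncol(mm)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  b <- setNames(opt$par, colnames(mm))
  list(fit = NULL, coef = b, scores = drop(mm %*% b),
       p = setNames(rep(NA_real_, length(b)), names(b)), separated = TRUE)
}

# Wald p-value per model term; for a factor, the smallest p among its
# indicator coefficients represents the term.
.term_p <- function(fit_obj, df, terms) {
  p <- fit_obj$p[-1] # drop intercept
  vapply(terms, function(tm) {
    cols <- if (is.factor(df[[tm]]) || is.character(df[[tm]])) {
      grep(paste0("^", tm), names(p), value = TRUE)
    } else tm
    min(p[cols], na.rm = TRUE)
  }, numeric(1))
}

#' Stepwise multivariable malignancy score
#'
#' Fits a binomial GLM (logit link) of malignancy on the candidate
#' features, then backward-eliminates the term with the largest Wald
#' p-value until every remaining term has `p <= p_stay`. Morphology
#' enters as indicator terms (solid as reference). Scores are the linear
#' predictor, evaluated in-sample by ROC/AUC. Perfect separation falls
#' back to a weakly ridge-penalized fit, flagged, without elimination
#' (Wald p-values are not defined there).
#'
#' @param features Tibble with the label column and candidate columns.
#' @param candidates Character vector of candidate terms, e.g.
#'   `c("nu_02", "morphology")`.
#' @param label_col Name of the benign/malignant label column.
#' @param p_stay Wald p-value above which a term is eliminated.
#' @return An object of class `malignancy_model`: `included`,
#'   `eliminated`, `coefficients`, `scores` (per complete-case nodule),
#'   `data` (complete cases used), `eval` (a `roc_eval` of the score),
#'   `penalized`, `p_stay`.
#' @export
multivariable_score <- function(features, candidates,
                                label_col = "malignancy", p_stay = 0.05) {
  missing_cols <- setdiff(c(candidates, label_col), names(features))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("Missing candidate column(s): %s.",
                            paste(missing_cols, collapse = ", ")))
  }
  df <- features[c(label_col, candidates)]
  ok <- !is.na(df[[label_col]])
  for (tm in candidates) {
    v <- df[[tm]]
    ok <- ok & !is.na(v) & (if (is.numeric(v)) is.finite(v) else TRUE)
  }
  df <- df[ok, , drop = FALSE]
  df[[label_col]] <- factor(.check_labels(df[[label_col]]),
                            levels = c("benign", "malignant"))
  for (tm in candidates) {
    if (is.character(df[[tm]])) {
      df[[tm]] <- factor(df[[tm]],
                         levels = intersect(.morphology_levels,
                                            unique(df[[tm]])))
    }
  }
  terms <- candidates
  eliminated <- character(0)
  repeat {
    if (length(terms) == 0) {
      return(structure(
        list(included = character(0), eliminated = eliminated,
             coefficients = NULL, scores = NULL, data = df, eval = NULL,
             penalized = FALSE, p_stay = p_stay, degenerate = TRUE),
        class = "malignancy_model"))
    }
    fo <- .fit_logistic(df, terms, label_col)
    if (fo$separated) break
    p_terms <- .term_p(fo, df, terms)
    worst <- names(which.max(p_terms))
    if (p_terms[worst] <= p_stay) break
    eliminated <- c(eliminated, worst)
    terms <- setdiff(terms, worst)
  }
  ev <- roc_auc(fo$scores, as.character(df[[label_col]]))
  structure(
    list(included = terms, eliminated = eliminated,
         coefficients = fo$coef, scores = fo$scores, data = df, eval = ev,
         penalized = fo$separated, p_stay = p_stay, degenerate = FALSE),
    class = "malignancy_model")
}

#' @export
print.malignancy_model <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Multivariable score: degenerate (all candidates eliminated)\n")
    return(invisible(x))
  }
  cat(sprintf("Multivariable malignancy score (%s)\n  terms: %s\n  AUC = %.3f%s\n",
              if (x$penalized) "penalized logistic" else "stepwise logistic",
              paste(x$included, collapse = " + "), x$eval$auc,
              if (length(x$eliminated) > 0)
                sprintf("   eliminated: %s", paste(x$eliminated, collapse = ", "))
              else ""))
  invisible(x)
}

#' @method tidy malignancy_model
#' @export
tidy.malignancy_model <- function(x, ...) {
  if (is.null(x$coefficients)) return(tibble::tibble())
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance malignancy_model
#' @export
glance.malignancy_model <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    return(tibble::tibble(auc = NA_real_, n_terms = 0L, penalized = FALSE,
                          degenerate = TRUE))
  }
  tibble::tibble(auc = x$eval$auc, n_terms = length(x$included),
                 penalized = x$penalized, degenerate = FALSE)
}

#' Rank-based group comparison
#'
#' Kruskal–Wallis omnibus test, with Holm-adjusted pairwise Wilcoxon
#' comparisons when more than two groups are present. Distributions here
#' are typically non-normal (see [normality_screen()]), so comparisons
#' are always rank-based.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 nonempty groups).
#' @param adjust Multiple-comparison adjustment for the pairwise tests.
#' @return A list of class `group_comparison`: `statistic`, `df`,
#'   `p_value`, `groups`, and (when > 2 groups) `pairwise`, a tibble of
#'   adjusted pairwise p-values.
#' @export
compare_groups <- function(values, groups, adjust = "holm") {
  groups <- factor(groups)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stop_validation("At least 2 groups are required.")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warn(sprintf("Group(s) with fewer than 2 observations: %s.",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  kw <- kruskal.test(values, groups)
  pairwise <- NULL
  if (nlevels(groups) > 2) {
    pw <- suppressWarnings(
      pairwise.wilcox.test(values, groups, p.adjust.method = adjust))
    pairwise <- tibble::as_tibble(as.table(pw$p.value), .name_repair =
                                    ~ c("group1", "group2", "p_adj"))
    pairwise <- pairwise[!is.na(pairwise$p_adj), ]
  }
  structure(
    list(statistic = unname(kw$statistic), df = unname(kw$parameter),
         p_value = kw$p.value, groups = levels(groups), pairwise = pairwise),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("Pairwise (Holm-adjusted):\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Normality screening report
#'
#' Kolmogorov–Smirnov comparison of each variable against a normal
#' distribution with matched mean and SD. This is a descriptive
#' screening report only: it never changes which test the pipeline runs
#' (group comparisons are always rank-based).
#'
#' @param features Tibble of numeric columns (non-numeric columns are
#'   skipped).
#' @param cols Columns to screen; default all numeric columns.
#' @return Tibble with `feature`, `statistic`, `p_value`, `n`.
#' @export
normality_screen <- function(features, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(features)[vapply(features, is.numeric, logical(1))]
  }
  purrr::list_rbind(purrr::map(cols, function(fc) {
    x <- features[[fc]]
    x <- x[is.finite(x)]
    if (length(x) < 3 || sd(x) == 0) {
      return(tibble::tibble(feature = fc, statistic = NA_real_,
                            p_value = NA_real_, n = length(x)))
    }
    ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    tibble::tibble(feature = fc, statistic = unname(ks$statistic),
                   p_value = ks$p.value, n = length(x))
  }))
}
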