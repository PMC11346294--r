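#' Plot longitudinal growth curves
#'
#' Observed volumes (points) with, optionally, the fitted growth-law
#' trajectories (lines).
#'
#' @param cohort A cohort tibble.
#' @param fits Optional tibble from [fit_growth()]; when given, fitted
#'   curves are drawn through each nodule's observation window.
#' @param log_scale Log-scale the volume axis.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(cohort, fits = NULL, log_scale = FALSE) {
  cohort <- as_cohort(cohort, rebase = FALSE)
  p <- ggplot2::ggplot(cohort,
                       ggplot2::aes(x = .data$time_months,
                                    y = .data$volume_mm3,
                                    group = .data$nodule_id,
                                    colour = .data$malignancy)) +
    ggplot2::geom_point()
  if (is.null(fits)) {
    p <- p + ggplot2::geom_line(alpha = 0.5)
  } else {
    curves <- cohort |>
      dplyr::summarise(t_max = max(.data$time_months),
                       v0 = .data$volume_mm3[which.min(.data$time_months)],
                       malignancy = .data$malignancy[1],
                       .by = "nodule_id") |>
      dplyr::inner_join(dplyr::select(fits, "nodule_id", "alpha", "beta"),
                        by = "nodule_id") |>
      dplyr::filter(!is.na(.data$beta))
    curve_pts <- purrr::list_rbind(purrr::map(seq_len(nrow(curves)), function(i) {
      r <- curves[i, ]
      tt <- seq(0, r$t_max, length.out = 50)
      tibble::tibble(nodule_id = r$nodule_id, malignancy = r$malignancy,
                     time_months = tt,
                     volume_mm3 = vb_solve_forward(r$v0, r$alpha, r$beta, tt))
    }))
    p <- p + ggplot2::geom_line(data = curve_pts, alpha = 0.6)
  }
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p + ggplot2::labs(x = "Months since first scan",
                    y = expression(Volume ~ (mm^3)), colour = NULL)
}

#' Box plot of growth exponents by group
#'
#' @param fits Tibble from [fit_growth()].
#' @param group Column of `fits` to group by (default `malignancy`).
#' @return A ggplot object.
#' @export
plot_beta_by_group <- function(fits, group = "malignancy") {
  fits <- dplyr::filter(fits, !is.na(.data$beta))
  ggplot2::ggplot(fits, ggplot2::aes(x = .data[[group]], y = .data$beta,
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(beta))
}

#' @describeIn roc_auc ROC curve plot for a single evaluation.
#' @param object A `roc_eval`.
#' @param ... Unused.
#' @method autoplot roc_eval
#' @export
autoplot.roc_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc))
}

#' Overlayed ROC curves for a feature evaluation table
#'
#' @param evaluations Tibble from [evaluate_features()] (needs the `roc`
#'   list-column).
#' @param features Subset of feature names to draw; default all.
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(evaluations, features = NULL) {
  if (!is.null(features)) {
    evaluations <- dplyr::filter(evaluations, .data$feature %in% features)
  }
  pts <- purrr::list_rbind(purrr::map(seq_len(nrow(evaluations)), function(i) {
    dplyr::mutate(evaluations$roc[[i]]$roc_points,
                  feature = sprintf("%s (AUC %.3f)",
                                    evaluations$feature[i],
                                    evaluations$auc[i]))
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$feature)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL)
}

#' Histogram of perturbation-refitted exponents
#'
#' @param object A `sensitivity_outcome`.
#' @param ... Unused.
#' @method autoplot sensitivity_outcome
#' @export
autoplot.sensitivity_outcome <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$beta_star)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$beta_ref, colour = "red") +
    ggplot2::geom_vline(xintercept = object$beta_median, linetype = "dashed") +
    ggplot2::labs(x = expression(beta^"*"), y = "Replicates")
}
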