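#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a weighted logistic regression fit
#'
#' @param x an `msi_wlr` fit.
#' @param ... unused.
#' @return tibble with one row per feature: `term`, `estimate`
#'   (standardised-scale coefficient), `abs_estimate`.
#' @export
tidy.msi_wlr <- function(x, ...) {
  tibble::tibble(term = sprintf("feature_%d", seq_along(x$coefficients)),
                 estimate = x$coefficients,
                 abs_estimate = abs(x$coefficients))
}

#' @rdname tidy.msi_wlr
#' @return for `glance()`: one-row tibble with `n`, `p`, `log_likelihood`,
#'   `regularization_strength`, `converged`.
#' @export
glance.msi_wlr <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, log_likelihood = x$log_likelihood,
                 regularization_strength = x$regularization_strength,
                 converged = x$converged)
}

#' Tidy a cross-validation result
#'
#' @param x an `msi_cv` object.
#' @param ... unused.
#' @return per-core out-of-fold predictions tibble.
#' @export
tidy.msi_cv <- function(x, ...) x$predictions

#' @rdname tidy.msi_cv
#' @return for `glance()`: one-row tibble of confusion counts, metric set
#'   and AUC.
#' @export
glance.msi_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(as.list(x$confusion)), x$metrics,
                   tibble::tibble(auc = x$auc))
}

#' Tidy a feature-selection result
#'
#' @param x an `msi_featsel` object.
#' @param ... unused.
#' @return per-feature tibble of test statistics, q-values and membership
#'   flags.
#' @export
tidy.msi_featsel <- function(x, ...) x$features

#' @rdname tidy.msi_featsel
#' @return for `glance()`: one-row tibble comparing full and reduced models.
#' @export
glance.msi_featsel <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$features),
                 n_selected = length(x$selected), alpha = x$alpha,
                 f1_full = x$cv_full$metrics$f1,
                 f1_reduced = x$cv_reduced$metrics$f1,
                 auc_full = x$cv_full$auc, auc_reduced = x$cv_reduced$auc)
}

#' ROC curve plot for a cross-validation result
#'
#' @param object an `msi_cv` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msi_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' ROC comparison plot for a feature-selection result
#'
#' Overlays the full-model and reduced-model ROC curves computed on the
#' same cross-validation folds.
#'
#' @param object an `msi_featsel` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msi_featsel <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$cv_full$roc,
                  model = sprintf("full (AUC %.3f)", object$cv_full$auc)),
    dplyr::mutate(object$cv_reduced$roc,
                  model = sprintf("reduced (AUC %.3f)", object$cv_reduced$auc)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                  colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ion or TIC image of a run
#'
#' @param run an `msi_run`.
#' @param feature optional mass-axis index; when `NULL` the total ion count
#'   is shown.
#' @return a ggplot raster of the pixel grid.
#' @export
plot_ion_image <- function(run, feature = NULL) {
  validate_msi_run(run)
  value <- if (is.null(feature)) tic(run) else run$intensities[, feature]
  lab <- if (is.null(feature)) "TIC" else sprintf("m/z %.4f", run$axis[feature])
  d <- dplyr::mutate(run$coords, value = value)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Segmentation map plot
#'
#' @param run an `msi_run`.
#' @param segmentation a `segmentation_map` from [segment_kmeans()].
#' @return a ggplot raster of cluster labels; background clusters are
#'   marked in the legend.
#' @export
plot_segmentation <- function(run, segmentation) {
  lab <- as.character(segmentation$cluster)
  bg <- segmentation$cluster %in% segmentation$background_clusters
  lab[bg] <- paste0(lab[bg], " (background)")
  d <- dplyr::mutate(run$coords, cluster = lab)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$cluster)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "cluster") +
    ggplot2::theme_minimal()
}
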