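#' Per-feature likelihood-ratio screening
#'
#' For each feature, fits a weighted single-feature logistic regression and
#' the weighted intercept-only model, and reports the likelihood-ratio
#' statistic `2 * (l1 - l0)` with a chi-square(1) p-value. This is the
#' multivariate arm of the two-pronged feature refinement: it asks whether a
#' feature carries any signal for the tumour/normal classification under the
#' same cost-sensitive likelihood the classifier maximises. A constant
#' feature yields statistic 0 and p-value 1. The fits are unpenalised
#' (up to a vanishing ridge of 1e-8 that keeps separable features finite;
#' the capped likelihood gap is unaffected at test precision).
#'
#' @param X cores x features matrix.
#' @param y 0/1 labels.
#' @param sample_weights per-core weights; default inverse-frequency class
#'   weights.
#' @return tibble: `feature`, `lrt_statistic`, `lrt_p`.
#' @export
lrt_per_feature <- function(X, y, sample_weights = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (is.null(sample_weights)) {
    cw <- class_weights(y)
    sample_weights <- unname(cw[as.character(y)])
  }
  w <- sample_weights
  # weighted intercept-only model has closed-form MLE p = weighted mean of y
  pbar <- sum(w * y) / sum(w)
  l0 <- sum(w * (y * log(pbar) + (1 - y) * log(1 - pbar)))
  stats <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (sd(x) == 0) return(0)
    fit <- fit_weighted_lr(cbind(x), y, sample_weights = w, lambda = 1e-8,
                           max_iter = 100)
    max(0, 2 * (fit$log_likelihood - l0))
  }, numeric(1))
  tibble::tibble(feature = seq_len(ncol(X)), lrt_statistic = stats,
                 lrt_p = pchisq(stats, df = 1, lower.tail = FALSE))
}

#' Per-feature Kruskal-Wallis tests
#'
#' The univariate arm of the feature refinement: a rank-based
#' (tie-corrected) Kruskal-Wallis test of each feature's intensities between
#' the tumour and normal groups, with chi-square(1) p-values. For two
#' groups, the H statistic is a monotone transform of the Mann-Whitney U.
#'
#' @param X cores x features matrix.
#' @param y 0/1 labels, both classes present.
#' @return tibble: `feature`, `kw_statistic`, `kw_p`.
#' @export
kruskal_wallis_per_feature <- function(X, y) {
  X <- as.matrix(X)
  g <- factor(as.integer(y), levels = c(0L, 1L))
  if (any(table(g) == 0)) {
    abort("both classes need at least one observation.",
          class = "msitma_validation_error")
  }
  res <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (length(unique(x)) == 1L) return(c(0, 1))  # all tied: H = 0
    kt <- kruskal.test(x, g)
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2))
  tibble::tibble(feature = seq_len(ncol(X)), kw_statistic = res[1, ],
                 kw_p = res[2, ])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate correction:
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, in the order of the
#' sorted p-values.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].", class = "msitma_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Two-pronged feature selection with refit on the same folds
#'
#' Combines the multivariate screen ([lrt_per_feature()], kept at raw
#' `p < alpha`) with the univariate screen ([kruskal_wallis_per_feature()]
#' under Benjamini-Hochberg control, `q < alpha`); the features significant
#' under both are the selected panel. The full model and the reduced model
#' (selected features only) are cross-validated on the *same* fold
#' assignment so their metrics are directly comparable. The absolute
#' standardised coefficients of the full-data fit are reported alongside as
#' an importance ranking.
#'
#' @param table a [core_feature_table()].
#' @param K,cv_seed,lambda cross-validation settings (see
#'   [cross_validate()]).
#' @param alpha significance threshold for both arms (default 0.05).
#' @return an `msi_featsel` object: `features` tibble (per-feature
#'   statistics, q-values, membership flags, `coef_rank` importance),
#'   `selected` (integer feature set), `cv_full`, `cv_reduced`.
#' @export
select_and_refit <- function(table, K = 10, cv_seed = 1, lambda = 1e-2,
                             alpha = 0.05) {
  stopifnot(inherits(table, "core_feature_table"))
  lrt <- lrt_per_feature(table$X, table$y)
  kw <- kruskal_wallis_per_feature(table$X, table$y)
  kw$kw_q <- bh_adjust(kw$kw_p)
  multivariate <- which(lrt$lrt_p < alpha)
  univariate <- which(kw$kw_q < alpha)
  selected <- intersect(multivariate, univariate)
  if (length(selected) == 0) {
    abort("no feature passed both selection arms; consider relaxing `alpha`.",
          class = "msitma_selection_error")
  }
  full_fit <- fit_weighted_lr(table$X, table$y, lambda = lambda)
  features <- dplyr::left_join(lrt, kw, by = "feature")
  features$mz <- table$axis
  features$abs_coef <- abs(full_fit$coefficients)
  features$coef_rank <- rank(-features$abs_coef, ties.method = "min")
  features$multivariate_significant <- features$feature %in% multivariate
  features$univariate_significant <- features$feature %in% univariate
  features$selected <- features$feature %in% selected

  folds <- slide_aware_stratified_folds(table$y, table$slide_ids, K, cv_seed)
  cv_full <- cross_validate(table, lambda = lambda, folds = folds)
  reduced <- core_feature_table(table$X[, selected, drop = FALSE], table$y,
                                table$slide_ids, table$patient_ids,
                                table$axis[selected])
  cv_reduced <- cross_validate(reduced, lambda = lambda, folds = folds)
  structure(list(features = features, selected = sort(selected),
                 alpha = alpha, cv_full = cv_full, cv_reduced = cv_reduced),
            class = "msi_featsel")
}

#' @export
print.msi_featsel <- function(x, ...) {
  cat(sprintf("<msi_featsel> %d/%d features selected (alpha = %g) | AUC full %.3f -> reduced %.3f\n",
              length(x$selected), nrow(x$features), x$alpha,
              x$cv_full$auc, x$cv_reduced$auc))
  invisible(x)
}
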