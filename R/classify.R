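#' Assemble a core feature table for modelling
#'
#' The modelling container: a cores-by-features intensity matrix with the
#' binary label (tumour = 1, normal = 0) and slide/patient bookkeeping.
#' Reference cores must already be excluded; both classes must be present.
#'
#' @param X numeric matrix, cores x features, non-negative.
#' @param y labels: 0/1 vector, or characters `"tumour"`/`"normal"`.
#' @param slide_ids,patient_ids per-core identifiers.
#' @param axis mass axis labelling the feature columns.
#' @return a `core_feature_table` list.
#' @export
core_feature_table <- function(X, y, slide_ids, patient_ids = NULL,
                               axis = NULL) {
  X <- as.matrix(X)
  if (is.character(y) || is.factor(y)) {
    y <- as.integer(as.character(y) == "tumour")
  }
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), length(slide_ids) == nrow(X))
  if (length(unique(y)) < 2) {
    abort("both classes must be present in a core feature table.",
          class = "msitma_validation_error")
  }
  if (any(!is.finite(X))) {
    abort("feature matrix must be finite.", class = "msitma_validation_error")
  }
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(nrow(X)))
  if (is.null(axis)) axis <- seq_len(ncol(X))
  structure(list(X = X, y = y, slide_ids = as.character(slide_ids),
                 patient_ids = as.character(patient_ids),
                 axis = as.numeric(axis)),
            class = "core_feature_table")
}

#' Build a core feature table from a core table
#'
#' Drops reference cores, encodes tumour = 1 / normal = 0, and stacks the
#' averaged spectra into the modelling matrix.
#'
#' @param core_table a core table from [average_core_spectra()] /
#'   [bind_core_tables()].
#' @param features optional integer subset of feature columns to keep.
#' @return a [core_feature_table()].
#' @export
as_core_feature_table <- function(core_table, features = NULL) {
  keep <- core_table$label %in% c("tumour", "normal")
  ct <- core_table[keep, , drop = FALSE]
  X <- do.call(rbind, ct$spectrum)
  axis <- attr(core_table, "axis")
  if (!is.null(features)) {
    X <- X[, features, drop = FALSE]
    axis <- axis[features]
  }
  core_feature_table(X, ct$label, ct$slide_id, ct$patient_id, axis)
}

#' Inverse-frequency class weights
#'
#' Cost-sensitive weighting for imbalanced data:
#' `weight_c = n_total / (2 * n_c)`, so that the two classes contribute
#' equally to the weighted likelihood and the weights average 1 under
#' balance. With 586 tumour and 73 normal cores this gives the minority
#' class a weight of about 4.51.
#'
#' @param y 0/1 label vector with both classes present.
#' @return named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
class_weights <- function(y) {
  y <- as.integer(y)
  n <- length(y)
  n1 <- sum(y == 1L); n0 <- n - n1
  if (n0 == 0 || n1 == 0) {
    abort("class_weights: both classes must be present.",
          class = "msitma_validation_error")
  }
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Fit a weighted L2-regularised logistic regression
#'
#' Maximises the weighted log-likelihood minus an L2 penalty
#' `lambda/2 * ||beta||^2` (intercept unpenalised) by Newton iterations with
#' step halving. Features are standardised internally (mean 0, sd 1;
#' constant columns untouched) and the transform stored, so predictions on
#' new data are consistent. The problem is convex, hence deterministic;
#' convergence is declared when the gradient norm drops below `tol`.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels.
#' @param sample_weights per-observation weights; defaults to the
#'   inverse-frequency class weights of [class_weights()].
#' @param lambda L2 penalty strength (default 1e-2). Per-core averaged MSI
#'   spectra are often linearly separable, so some ridge keeps the optimum
#'   finite.
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return an `msi_wlr` fit: coefficients (standardised scale), intercept,
#'   the standardisation transform, class weights used, `log_likelihood`
#'   (weighted, unpenalised), and `converged`.
#' @export
fit_weighted_lr <- function(X, y, sample_weights = NULL, lambda = 1e-2,
                            max_iter = 200, tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (any(!is.finite(X))) {
    abort("X must be finite.", class = "msitma_validation_error")
  }
  n <- nrow(X); p <- ncol(X)
  cw <- NULL
  if (is.null(sample_weights)) {
    cw <- class_weights(y)
    sample_weights <- unname(cw[as.character(y)])
  }
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  Z1 <- cbind(1, Z)

  beta <- rep(0, p + 1)
  pen <- c(0, rep(lambda, p))
  w <- sample_weights
  loglik <- function(b) {
    eta <- drop(Z1 %*% b)
    softplus <- pmax(eta, 0) + log1p(exp(-abs(eta)))  # overflow-safe
    sum(w * (y * eta - softplus))
  }
  obj <- function(b) loglik(b) - sum(pen * b^2) / 2
  cur <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Z1 %*% beta)
    prob <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(Z1, w * (y - prob))) - pen * beta
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    wdiag <- pmax(w * prob * (1 - prob), 1e-10)
    H <- crossprod(Z1 * wdiag, Z1)
    diag(H) <- diag(H) + pen
    delta <- tryCatch(solve(H, grad), error = function(e) grad)
    step <- 1
    for (half in 1:40) {
      cand <- beta + step * delta
      val <- obj(cand)
      if (is.finite(val) && val > cur) { beta <- cand; cur <- val; break }
      step <- step / 2
    }
  }
  structure(list(coefficients = beta[-1], intercept = beta[1],
                 feature_means = mu, feature_sds = sigma,
                 class_weights = cw, sample_weights = sample_weights,
                 regularization_strength = lambda,
                 log_likelihood = loglik(beta),
                 converged = converged, n = n, p = p),
            class = "msi_wlr")
}

#' @export
print.msi_wlr <- function(x, ...) {
  cat(sprintf("<msi_wlr> %d features, n = %d, lambda = %g, loglik = %.3f%s\n",
              x$p, x$n, x$regularization_strength, x$log_likelihood,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Predict tumour probabilities from a weighted LR fit
#'
#' @param object an `msi_wlr` fit.
#' @param newdata feature matrix on the original (unstandardised) scale.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.msi_wlr <- function(object, newdata, ...) {
  Z <- sweep(sweep(as.matrix(newdata), 2, object$feature_means), 2,
             object$feature_sds, "/")
  eta <- drop(Z %*% object$coefficients) + object$intercept
  1 / (1 + exp(-eta))
}

#' Slide-aware stratified cross-validation folds
#'
#' Stratifies on class so every fold's test-set class ratio is within one
#' core of the global ratio, then greedily repairs folds whose test set is
#' confined to a single slide: whenever the dataset has at least two
#' slides, same-class cores are swapped between folds (lowest core index
#' first) until every fold's test set spans at least two slides. Training
#' sets always retain both classes because `K >= 2` and no fold can hold an
#' entire class. Deterministic under `seed`.
#'
#' @param y 0/1 labels.
#' @param slide_ids per-core slide identifiers.
#' @param K number of folds (default 10); must not exceed either class
#'   count.
#' @param seed integer seed.
#' @return integer fold assignment in `1..K`, one entry per core.
#' @export
slide_aware_stratified_folds <- function(y, slide_ids, K = 10, seed = 1) {
  y <- as.integer(y)
  n <- length(y)
  stopifnot(length(slide_ids) == n)
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (K < 2) abort("K must be at least 2.", class = "msitma_config_error")
  if (any(counts < K)) {
    abort(sprintf("K = %d exceeds a class count (normal = %d, tumour = %d).",
                  K, counts[["0"]], counts[["1"]]),
          class = "msitma_config_error")
  }
  folds <- integer(n)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(K), length(idx))
    }
  })
  n_slides <- length(unique(slide_ids))
  if (n_slides >= 2) {
    repeat {
      span <- vapply(seq_len(K), function(k) {
        length(unique(slide_ids[folds == k]))
      }, integer(1))
      bad <- which(span < 2)
      if (length(bad) == 0) break
      k <- bad[1]
      fixed <- FALSE
      in_k <- which(folds == k)
      lone_slide <- slide_ids[in_k[1]]
      for (i in in_k[order(in_k)]) {
        donors <- which(folds != k & y == y[i] & slide_ids != lone_slide)
        donors <- donors[vapply(donors, function(d) {
          # the donor fold must keep >= 2 slides after the swap
          df <- folds[d]
          rest <- slide_ids[folds == df & seq_len(n) != d]
          length(unique(c(rest, slide_ids[i]))) >= 2 || n_slides < 2
        }, logical(1))]
        if (length(donors) > 0) {
          d <- donors[order(donors)][1]
          folds[c(i, d)] <- c(folds[d], k)
          fixed <- TRUE
          break
        }
      }
      if (!fixed) {
        abort(sprintf("cannot make fold %d span two slides; slide layout too restrictive.", k),
              class = "msitma_config_error")
      }
    }
  }
  folds
}

#' Classification metrics from a confusion matrix
#'
#' @param tp,fp,tn,fn confusion counts at a fixed decision threshold.
#' @return one-row tibble: `tpr`, `tnr`, `fpr`, `balanced_accuracy`, `f1`.
#'   Identities `fpr = 1 - tnr` and `balanced_accuracy = (tpr + tnr) / 2`
#'   hold by construction.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  for (v in c(tp, fp, tn, fn)) assert_scalar_number(v, "confusion count", min = 0)
  if (tp + fn < 1 || tn + fp < 1) {
    abort("each true class must contain at least one core.",
          class = "msitma_validation_error")
  }
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  tibble::tibble(tpr = tpr, tnr = tnr, fpr = 1 - tnr,
                 balanced_accuracy = (tpr + tnr) / 2,
                 f1 = 2 * tp / (2 * tp + fp + fn))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique predicted probabilities
#' (ties grouped) and reports the (FPR, TPR) staircase plus the trapezoidal
#' area under it. With ties handled by grouping, the trapezoidal AUC equals
#' the Mann-Whitney concordance probability exactly.
#'
#' @param y 0/1 labels with both classes present.
#' @param prob predicted probabilities (any monotone score works).
#' @return list with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(y, prob) {
  y <- as.integer(y)
  stopifnot(length(y) == length(prob))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0 || n_neg == 0) {
    abort("roc_curve: both classes must be present.",
          class = "msitma_validation_error")
  }
  ord <- order(prob, decreasing = TRUE)
  ys <- y[ord]; ps <- prob[ord]
  grp <- cumsum(!duplicated(ps))
  tp <- cumsum(ys == 1L); fp <- cumsum(ys == 0L)
  last <- which(!duplicated(grp, fromLast = TRUE))
  points <- tibble::tibble(threshold = ps[last],
                           fpr = fp[last] / n_neg, tpr = tp[last] / n_pos)
  points <- dplyr::bind_rows(tibble::tibble(threshold = Inf, fpr = 0, tpr = 0),
                             points)
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Slide-aware cross-validated weighted logistic regression
#'
#' Runs stratified K-fold cross-validation (folds from
#' [slide_aware_stratified_folds()], or supplied) of the cost-sensitive
#' L2-regularised logistic regression: within each fold, class weights and
#' feature standardisation are recomputed on the training cores only, and
#' out-of-fold probabilities are predicted for the held-out cores. The
#' confusion matrix is taken at `threshold` (default 0.5) and the ROC is
#' swept over the out-of-fold probabilities.
#'
#' @param table a [core_feature_table()].
#' @param K number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param lambda L2 penalty (default 1e-2).
#' @param threshold decision threshold for the confusion matrix.
#' @param folds optional precomputed fold assignment (overrides `K`/`seed`),
#'   e.g. to evaluate a reduced model on the same folds as the full one.
#' @return an `msi_cv` object: `predictions` tibble (`core`, `y`, `slide_id`,
#'   `fold`, `prob`, `pred`), `confusion`, `metrics`, `roc`, `auc`,
#'   `fold_assignment`.
#' @export
cross_validate <- function(table, K = 10, seed = 1, lambda = 1e-2,
                           threshold = 0.5, folds = NULL) {
  stopifnot(inherits(table, "core_feature_table"))
  if (is.null(folds)) {
    folds <- slide_aware_stratified_folds(table$y, table$slide_ids, K, seed)
  }
  K_eff <- max(folds)
  prob <- rep(NA_real_, length(table$y))
  for (k in seq_len(K_eff)) {
    test <- folds == k
    fit <- fit_weighted_lr(table$X[!test, , drop = FALSE], table$y[!test],
                           lambda = lambda)
    prob[test] <- predict(fit, table$X[test, , drop = FALSE])
  }
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1L & table$y == 1L)
  fp <- sum(pred == 1L & table$y == 0L)
  tn <- sum(pred == 0L & table$y == 0L)
  fn <- sum(pred == 0L & table$y == 1L)
  roc <- roc_curve(table$y, prob)
  structure(list(
    predictions = tibble::tibble(core = seq_along(table$y), y = table$y,
                                 slide_id = table$slide_ids,
                                 fold = folds, prob = prob, pred = pred),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    metrics = compute_metrics(tp, fp, tn, fn),
    roc = roc$points, auc = roc$auc,
    fold_assignment = folds, threshold = threshold, lambda = lambda),
    class = "msi_cv")
}

#' @export
print.msi_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<msi_cv> %d cores, %d folds | TPR %.3f TNR %.3f FPR %.3f bal.acc %.3f F1 %.3f AUC %.3f\n",
    nrow(x$predictions), max(x$fold_assignment), m$tpr, m$tnr, m$fpr,
    m$balanced_accuracy, m$f1, x$auc))
  invisible(x)
}

#' PCA of core spectra with per-component class separation tests
#'
#' Principal component analysis on the mean-centred core spectra, followed
#' by a two-sided Mann-Whitney test of tumour vs normal scores on each of
#' the first `n_components` components. The reported `u` follows the
#' min-rank convention, `min(U_xy, U_yx)`, so complete separation gives
#' `u = 0` regardless of direction; `statistic` is the raw `U` of the
#' normal-class scores over the tumour-class scores. Exact p-values are
#' used where `stats::wilcox.test` provides them (no ties, small n), the
#' tie-corrected continuity-corrected normal approximation otherwise.
#'
#' @param table a [core_feature_table()].
#' @param n_components number of leading components to report (default 3).
#' @return list with `scores` tibble (core, label, `PC1..`), tibble
#'   `components` (`component`, `explained_variance`, `statistic`, `u`,
#'   `p_value`), and the `prcomp` fit.
#' @export
pca_separation <- function(table, n_components = 3) {
  stopifnot(inherits(table, "core_feature_table"))
  if (nrow(table$X) < n_components + 1) {
    abort("need at least n_components + 1 cores.",
          class = "msitma_validation_error")
  }
  if (all(apply(table$X, 2, sd) == 0)) {
    abort("constant feature matrix.", class = "msitma_validation_error")
  }
  fit <- prcomp(table$X, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(fit$x))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  comps <- lapply(seq_len(n_components), function(j) {
    s <- fit$x[, j]
    a <- s[table$y == 0L]; b <- s[table$y == 1L]
    wt <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
    u <- unname(wt$statistic)
    tibble::tibble(component = j, explained_variance = ev[j],
                   statistic = u,
                   u = min(u, length(a) * length(b) - u),
                   p_value = wt$p.value)
  })
  scores <- tibble::as_tibble(fit$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(core = seq_len(nrow(table$X)),
                   label = ifelse(table$y == 1L, "tumour", "normal")),
    scores)
  list(scores = scores, components = dplyr::bind_rows(comps), prcomp = fit)
}
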