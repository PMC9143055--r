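test_that("inverse-frequency class weights follow n / (2 n_c)", {
  expect_equal(unname(class_weights(c(rep(1, 50), rep(0, 50)))), c(1, 1))
  w <- class_weights(c(rep(1, 80), rep(0, 20)))
  expect_equal(unname(w), c(100 / 40, 100 / 160))  # normal 2.5, tumour 0.625
  w2 <- class_weights(c(rep(1, 586), rep(0, 73)))
  expect_equal(unname(w2[["0"]]), 659 / (2 * 73))
  expect_equal(unname(w2[["0"]]), 4.51, tolerance = 0.01)
  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("weighted LR honours sign, symmetry and parameter recovery", {
  # perfectly correlated single feature: positive coefficient even under
  # strong shrinkage
  y <- c(0, 0, 1, 1)
  fit <- fit_weighted_lr(cbind(c(-1, -1, 1, 1)), y,
                         sample_weights = rep(1, 4), lambda = 10)
  expect_gt(fit$coefficients[1], 0)
  # symmetric toy: probability at x = 0 is exactly 0.5
  fit2 <- fit_weighted_lr(cbind(c(-1, -1, 1, 1)), y,
                          sample_weights = rep(1, 4), lambda = 1e-6)
  expect_equal(unname(predict(fit2, cbind(0))), 0.5, tolerance = 1e-6)
  expect_true(fit2$converged)

  # parameter recovery at n = 2000, true beta = (1.5, -2)
  set.seed(77)
  n <- 2000
  X <- cbind(rnorm(n), rnorm(n))
  eta <- 0.3 + X %*% c(1.5, -2)
  yy <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit3 <- fit_weighted_lr(X, yy, sample_weights = rep(1, n), lambda = 1e-4)
  beta_orig <- fit3$coefficients / fit3$feature_sds
  expect_equal(unname(beta_orig), c(1.5, -2), tolerance = 0.1)
})

test_that("weighted LR agrees with glm on a weighted low-penalty fit", {
  set.seed(5)
  n <- 300
  X <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, 1 / (1 + exp(-(0.5 + X %*% c(1, -0.5)))))
  w <- ifelse(y == 1, 0.7, 1.9)
  fit <- fit_weighted_lr(X, y, sample_weights = w, lambda = 1e-10)
  ref <- suppressWarnings(glm(y ~ X, family = binomial, weights = w))
  beta_orig <- fit$coefficients / fit$feature_sds
  expect_equal(unname(beta_orig), unname(coef(ref)[2:3]), tolerance = 1e-4)
  expect_equal(unname(predict(fit, X)),
               unname(fitted(ref)), tolerance = 1e-5)
})

test_that("folds are stratified, slide-spanning and deterministic", {
  y <- c(rep(1, 80), rep(0, 20))
  slides <- rep(sprintf("S%d", 1:4), 25)
  f <- slide_aware_stratified_folds(y, slides, K = 10, seed = 2)
  expect_equal(sort(unique(f)), 1:10)
  for (k in 1:10) {
    expect_equal(sum(f == k & y == 1), 8)   # exact divisibility
    expect_equal(sum(f == k & y == 0), 2)
    expect_gte(length(unique(slides[f == k])), 2)
    expect_equal(sort(unique(y[f != k])), c(0, 1))  # training keeps both
  }
  expect_identical(f, slide_aware_stratified_folds(y, slides, K = 10, seed = 2))
  expect_false(identical(f, slide_aware_stratified_folds(y, slides, 10, 3)))
  # per-fold class ratio within one core of the global ratio, uneven case
  y2 <- c(rep(1, 83), rep(0, 21))
  slides2 <- rep(sprintf("S%d", 1:4), 26)
  f2 <- slide_aware_stratified_folds(y2, slides2, K = 10, seed = 1)
  for (k in 1:10) {
    expect_lte(abs(sum(f2 == k & y2 == 1) - 8.3), 1)
    expect_lte(abs(sum(f2 == k & y2 == 0) - 2.1), 1)
  }
  # three slides: every fold's test cores span >= 2 slides
  sim <- simulate_core_table(n_cores = 120, n_features = 10, n_slides = 3,
                             seed = 3)
  f3 <- slide_aware_stratified_folds(sim$table$y, sim$table$slide_ids,
                                     K = 10, seed = 1)
  for (k in 1:10) {
    expect_gte(length(unique(sim$table$slide_ids[f3 == k])), 2)
  }
  expect_error(slide_aware_stratified_folds(y, slides, K = 30, seed = 1),
               "class count")
})

test_that("metric arithmetic and identities hold", {
  m <- compute_metrics(tp = 95, fp = 3, tn = 97, fn = 5)
  expect_equal(m$tpr, 0.95)
  expect_equal(m$tnr, 0.97)
  expect_equal(m$fpr, 0.03)
  expect_equal(m$balanced_accuracy, 0.96)
  perfect <- compute_metrics(10, 0, 40, 0)
  expect_equal(unname(unlist(perfect[c("tpr", "tnr", "balanced_accuracy",
                                       "f1")])), rep(1, 4))
  expect_equal(perfect$fpr, 0)
  allpos <- compute_metrics(25, 25, 0, 0)
  expect_equal(allpos$tpr, 1)
  expect_equal(allpos$tnr, 0)
  expect_equal(allpos$balanced_accuracy, 0.5)
  # identities on random confusions
  set.seed(9)
  for (i in 1:20) {
    cm <- sample(0:50, 4, replace = TRUE) + 1
    m <- compute_metrics(cm[1], cm[2], cm[3], cm[4])
    expect_equal(m$fpr, 1 - m$tnr)
    expect_equal(m$balanced_accuracy, (m$tpr + m$tnr) / 2)
  }
  expect_error(compute_metrics(0, 1, 1, 0), "at least one")
})

test_that("trapezoid AUC equals the pairwise concordance oracle", {
  concordance <- function(y, p) {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  set.seed(11)
  for (i in 1:15) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(30), 2)  # rounding forces ties
    r <- roc_curve(y, p)
    expect_equal(r$auc, concordance(y, p), tolerance = 1e-12)
    # invariant under strictly monotone transforms of the scores
    expect_equal(roc_curve(y, plogis(5 * p - 2))$auc, r$auc,
                 tolerance = 1e-12)
  }
  expect_equal(roc_curve(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_error(roc_curve(rep(1, 5), runif(5)), "both classes")
})

test_that("cross-validation separates strong markers and stays null without them", {
  sim <- simulate_core_table(n_cores = 120, n_features = 30, n_markers = 5,
                             marker_log2_effect = 2, noise_sd = 0.3,
                             seed = 41)
  cv <- cross_validate(sim$table, K = 10, seed = 1)
  expect_gte(cv$metrics$f1, 0.95)
  expect_gte(cv$auc, 0.99)
  expect_equal(sum(cv$confusion), 120)
  expect_true(all(table(cv$fold_assignment) > 0))
  expect_false(any(is.na(cv$predictions$prob)))

  null_sim <- simulate_core_table(n_cores = 120, n_features = 30,
                                  marker_log2_effect = 0, seed = 42)
  cv0 <- cross_validate(null_sim$table, K = 10, seed = 1)
  expect_lt(abs(cv0$auc - 0.5), 0.25)
})

test_that("out-of-fold probabilities never see the core's own label", {
  sim <- simulate_core_table(n_cores = 60, n_features = 10, seed = 8)
  cv <- cross_validate(sim$table, K = 5, seed = 2)
  flip <- sim$table
  i <- 7
  flip$y[i] <- 1L - flip$y[i]
  # keep the fold layout identical to isolate the leak question
  cv2 <- cross_validate(flip, folds = cv$fold_assignment)
  expect_equal(cv$predictions$prob[i], cv2$predictions$prob[i],
               tolerance = 1e-12)
})

test_that("class weighting shrinks the TPR-TNR gap on imbalanced data", {
  gaps <- vapply(1:20, function(s) {
    sim <- simulate_core_table(n_cores = 90, n_features = 15, n_markers = 3,
                               marker_log2_effect = 0.6, noise_sd = 0.5,
                               tumour_fraction = 8 / 9, seed = 100 + s)
    tab <- sim$table
    fit_w <- fit_weighted_lr(tab$X, tab$y, lambda = 1e-2)
    fit_u <- fit_weighted_lr(tab$X, tab$y,
                             sample_weights = rep(1, length(tab$y)),
                             lambda = 1e-2)
    gap <- function(fit) {
      pred <- as.integer(predict(fit, tab$X) >= 0.5)
      m <- compute_metrics(sum(pred & tab$y), sum(pred & !tab$y),
                           sum(!pred & !tab$y), sum(!pred & tab$y))
      abs(m$tpr - m$tnr)
    }
    c(weighted = gap(fit_w), unweighted = gap(fit_u))
  }, numeric(2))
  expect_lt(mean(gaps["weighted", ]), mean(gaps["unweighted", ]))
})

test_that("PCA separation reports min-rank U and detects separated classes", {
  # complete separation: {1,2,3} vs {4,5,6} gives U = 0 under min-rank
  X <- cbind(c(1, 2, 3, 4, 5, 6), rnorm(6, 0, 1e-3))
  tab <- core_feature_table(X - min(X) + 1, c(0, 0, 0, 1, 1, 1),
                            slide_ids = rep("S", 6))
  ps <- pca_separation(tab, n_components = 2)
  expect_equal(ps$components$u[1], 0)
  expect_true(all(diff(ps$components$explained_variance) <= 1e-12))

  sim <- simulate_core_table(n_cores = 60, n_features = 20, n_markers = 8,
                             marker_log2_effect = 2, noise_sd = 0.2,
                             slide_batch_sd = 0, seed = 12)
  ps2 <- pca_separation(sim$table, n_components = 3)
  expect_lt(min(ps2$components$p_value), 0.05)
  expect_error(pca_separation(core_feature_table(
    matrix(1, 10, 3), rep(c(0, 1), 5), rep("S", 10))), "constant")
})

test_that("tidy and glance methods expose the modelling results", {
  sim <- simulate_core_table(n_cores = 60, n_features = 10, seed = 6)
  fit <- fit_weighted_lr(sim$table$X, sim$table$y)
  expect_equal(nrow(tidy(fit)), 10)
  expect_equal(glance(fit)$p, 10)
  cv <- cross_validate(sim$table, K = 5, seed = 1)
  expect_equal(nrow(tidy(cv)), 60)
  g <- glance(cv)
  expect_equal(g$tp + g$fp + g$tn + g$fn, 60)
  expect_s3_class(autoplot(cv), "ggplot")
})
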