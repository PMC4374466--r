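test_that("feature matrices have the documented dimensionality per mode", {
  sess <- cached_session(60, seed = 13)
  ts <- build_trialset(sess$preprocessed, sess$events)
  fm_t <- build_feature_matrix(ts, mode = "time")
  expect_equal(ncol(fm_t$X), 28 * 358)
  fm_f <- build_feature_matrix(ts, mode = "freq")
  expect_equal(ncol(fm_f$X), 28 * 40)
  fm_b <- build_feature_matrix(ts, mode = "both")
  expect_equal(ncol(fm_b$X), 28 * 358 + 28 * 40)
  fm_s <- build_feature_matrix(ts, mode = "time", channels = "stick")
  expect_equal(ncol(fm_s$X), 2 * 358)
  fm_e <- build_feature_matrix(ts, mode = "time", channels = "eog")
  expect_equal(ncol(fm_e$X), 3 * 358)
  expect_true(all(is.finite(fm_b$X)))
  # time features are the raw epoch samples in the 0.2-0.9 s range
  rel <- errpdetect:::sample_range(0.2, 0.9, 512)
  expect_equal(fm_t$X[1, 1:358], ts$epochs[1, 1, rel])
})

test_that("class balancing down-samples the majority class reproducibly", {
  set.seed(1)
  fm <- structure(list(X = matrix(rnorm(683 * 4), 683),
                       labels = rep(c("execution", "outcome"), c(597, 86)),
                       severity = rep(NA_real_, 683),
                       feature_names = paste0("f", 1:4), mode = "time"),
                  class = "feature_matrix")
  b1 <- balance_classes(fm, seed = 4)
  expect_equal(unname(table(b1$labels)), c(86L, 86L),
               ignore_attr = TRUE)
  b2 <- balance_classes(fm, seed = 4)
  expect_identical(b1$X, b2$X)
  # already balanced input is returned unchanged
  fmb <- errpdetect:::subset_fm(fm, c(1:86, 598:683))
  expect_identical(balance_classes(fmb, seed = 1)$X, fmb$X)
  fm_empty <- errpdetect:::subset_fm(fm, 1:597)
  expect_error(balance_classes(fm_empty), "2 classes")
})

test_that("the linear SVM separates separable data and is margin-invariant to duplicate features", {
  set.seed(6)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 5), 20))
  y <- rep(c("a", "b"), each = 20)
  m <- train_linear_classifier(X, y)
  expect_equal(mean(predict(m, X)$labels == y), 1)
  expect_error(train_linear_classifier(X, rep("a", 40)), "single class")
  # duplicating a feature must not change predictions on well-margined data
  set.seed(7)
  Xt <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30))
  yt <- rep(c("a", "b"), each = 30)
  Xnew <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 3), 10))
  m1 <- train_linear_classifier(Xt, yt)
  m2 <- train_linear_classifier(cbind(Xt, Xt[, 2]), yt)
  expect_equal(predict(m1, Xnew)$labels,
               predict(m2, cbind(Xnew, Xnew[, 2]))$labels)
})

test_that("cross-validation is honest: chance on permuted labels, perfect on separable data", {
  set.seed(10)
  n <- 120
  X <- matrix(rnorm(n * 10), n)
  y <- sample(rep(c("a", "b"), each = n / 2))
  cv <- crossvalidate(structure(list(X = X, labels = y,
                                     severity = rep(NA_real_, n),
                                     feature_names = NULL, mode = "time"),
                                class = "feature_matrix"),
                      k = 10, seed = 2)
  band <- 1.96 * sqrt(0.25 / n)
  expect_gt(cv$accuracy, 0.5 - 2 * band)
  expect_lt(cv$accuracy, 0.5 + 2 * band)

  # leave-one-out on 20 well-separated trials is perfect
  Xs <- rbind(matrix(rnorm(20, 0, 0.2), 10), matrix(rnorm(20, 4, 0.2), 10))
  ys <- rep(c("a", "b"), each = 10)
  fms <- structure(list(X = Xs, labels = ys, severity = rep(NA_real_, 20),
                        feature_names = NULL, mode = "time"),
                   class = "feature_matrix")
  expect_equal(crossvalidate(fms, k = 10, seed = 1)$accuracy, 1)
  expect_error(crossvalidate(fms, k = 1), "at least 2")
})

test_that("fold-internal standardization never uses test-fold statistics", {
  set.seed(20)
  n <- 60
  X <- rbind(matrix(rnorm(n / 2 * 4, 0), n / 2),
             matrix(rnorm(n / 2 * 4, 2), n / 2))
  y <- rep(c("a", "b"), each = n / 2)
  fm <- structure(list(X = X, labels = y, severity = rep(NA_real_, n),
                       feature_names = NULL, mode = "time"),
                  class = "feature_matrix")
  cv_clean <- crossvalidate(fm, k = 5, seed = 3)
  # spike one trial to an extreme outlier; in the fold where it is test data
  # the training set is unchanged, so leak-free standardization implies the
  # other test trials of that fold classify identically
  fm_spiked <- fm
  fm_spiked$X[7, ] <- 1e6
  cv_spiked <- crossvalidate(fm_spiked, k = 5, seed = 3)
  expect_identical(cv_clean$folds, cv_spiked$folds)
  f7 <- cv_clean$folds[7]
  sz <- sum(cv_clean$folds == f7)
  n_changed <- round(abs(cv_clean$per_fold[f7] - cv_spiked$per_fold[f7]) * sz)
  expect_lte(n_changed, 1)
})

test_that("the permutation threshold sits just above chance for a null dataset", {
  set.seed(30)
  n <- 80
  X <- matrix(rnorm(n * 6), n)
  y <- rep(c("a", "b"), each = n / 2)
  fm <- structure(list(X = X, labels = y, severity = rep(NA_real_, n),
                       feature_names = NULL, mode = "time"),
                  class = "feature_matrix")
  expect_warning(pt <- permutation_threshold(fm, n_perm = 15, k = 5, seed = 1),
                 "few permutations")
  pt <- permutation_threshold(fm, n_perm = 60, alpha = 0.05, k = 5, seed = 1)
  expect_gt(pt$threshold, 0.5)
  expect_lt(pt$threshold, 0.5 + 3 * 1.96 * sqrt(0.25 / n))
  # alpha = 1 returns the minimum permuted accuracy
  pt1 <- permutation_threshold(fm, n_perm = 20, alpha = 1, k = 5, seed = 1)
  expect_equal(pt1$threshold, min(pt1$permuted_accuracies))
})

test_that("error detectability orders as outcome > execution against no-error trials", {
  sess <- cached_session(1200, snr_scale = 2, seed = 301)
  ts <- build_trialset(sess$preprocessed, sess$events)
  acc <- sapply(c("outcome", "execution"), function(kind) {
    keep <- ts$labels %in% c(kind, "noError")
    fm <- build_feature_matrix(errpdetect:::subset_trialset(ts, keep),
                               mode = "freq")
    crossvalidate(balance_classes(fm, seed = 5), k = 5, seed = 5)$accuracy
  })
  expect_gt(acc["outcome"], acc["execution"])
})

test_that("severity contrasts skip under-populated pairs and handle single severities", {
  sess <- cached_session(60, seed = 13)
  ts <- build_trialset(sess$preprocessed, sess$events)
  # ~7 execution trials in 60 s: every pair lacks 10-fold support
  expect_message(res <- severity_contrasts(ts, k = 10), "skipped")
  expect_true(all(is.na(res$accuracy)))
})
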