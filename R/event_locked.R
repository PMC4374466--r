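# Event-locked classification: feature building, class balancing, linear SVM
# (libsvm via e1071), stratified 10-fold cross-validation, permutation
# significance, and severity / confound contrasts.

#' Build the event-locked feature matrix from a trial set
#'
#' Time-domain features are the raw samples of every selected channel in the
#' 0.2-0.9 s post-event range (358 samples per channel at 512 Hz under the
#' half-open convention); frequency-domain features are the first 40 Welch
#' bins per channel computed on the same range; `"both"` concatenates the
#' two.
#'
#' @param ts A `trialset` whose window covers `time_range`.
#' @param mode `"time"`, `"freq"` or `"both"`.
#' @param channels `"eeg"` (default), `"eog"` or `"stick"` — the confound
#'   analyses classify on EOG or thumbstick channels alone.
#' @param time_range Post-event range in seconds (half-open).
#' @param n_freq_bins Number of leading Welch bins kept per channel.
#' @return A `feature_matrix`: list with `X` (trials x features), `labels`,
#'   `severity`, `feature_names`, `mode`.
#' @export
build_feature_matrix <- function(ts, mode = c("both", "time", "freq"),
                                 channels = "eeg",
                                 time_range = c(0.2, 0.9),
                                 n_freq_bins = 40) {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "trialset"))
  if (time_range[1] < ts$window[1] || time_range[2] > ts$window[2])
    stop("trial window does not cover the requested time range")
  ch_idx <- which(ts$channel_kinds %in% channels)
  if (!length(ch_idx)) stop("no channels of kind: ", paste(channels, collapse = ","))
  rel <- sample_range(time_range[1] - ts$window[1],
                      time_range[2] - ts$window[1], ts$fs_Hz)
  n_tr <- dim(ts$epochs)[1]
  ch_lab <- ts$channel_labels[ch_idx]

  blocks <- list()
  names_out <- character(0)
  if (mode %in% c("time", "both")) {
    Xt <- matrix(0, n_tr, length(ch_idx) * length(rel))
    for (t in seq_len(n_tr))
      Xt[t, ] <- as.numeric(t(ts$epochs[t, ch_idx, rel]))
    blocks <- c(blocks, list(Xt))
    names_out <- c(names_out,
                   as.vector(t(outer(ch_lab, seq_along(rel),
                                     function(c, i) paste0(c, "_t", i)))))
  }
  if (mode %in% c("freq", "both")) {
    # stack trials*channels as columns for one vectorized Welch call
    seg <- matrix(0, length(rel), n_tr * length(ch_idx))
    k <- 0
    for (t in seq_len(n_tr)) for (c in ch_idx) {
      k <- k + 1
      seg[, k] <- ts$epochs[t, c, rel]
    }
    P <- welch_psd(seg, ts$fs_Hz)$power[seq_len(n_freq_bins), , drop = FALSE]
    Xf <- matrix(0, n_tr, length(ch_idx) * n_freq_bins)
    for (t in seq_len(n_tr)) {
      cols <- (t - 1) * length(ch_idx) + seq_along(ch_idx)
      Xf[t, ] <- as.numeric(P[, cols])    # bin-major within channel
    }
    blocks <- c(blocks, list(Xf))
    names_out <- c(names_out,
                   as.vector(outer(seq_len(n_freq_bins), ch_lab,
                                   function(i, c) paste0(c, "_f", i - 1))))
  }
  X <- do.call(cbind, blocks)
  if (!all(is.finite(X))) stop("non-finite feature values")
  structure(list(X = X, labels = ts$labels, severity = ts$severity,
                 feature_names = names_out, mode = mode),
            class = "feature_matrix")
}

subset_fm <- function(fm, idx) {
  structure(list(X = fm$X[idx, , drop = FALSE], labels = fm$labels[idx],
                 severity = fm$severity[idx],
                 feature_names = fm$feature_names, mode = fm$mode),
            class = "feature_matrix")
}

#' Down-sample the majority class to the minority size
#'
#' Pure subsampling (uniform at random, seeded); fits no statistics, so it
#' may be applied globally or inside cross-validation folds without leakage.
#'
#' @param fm A `feature_matrix` with a binary label.
#' @param seed Integer seed.
#' @return Balanced `feature_matrix`.
#' @export
balance_classes <- function(fm, seed = 1L) {
  cls <- unique(fm$labels)
  if (length(cls) != 2) stop("balance_classes needs exactly 2 classes")
  n <- table(factor(fm$labels, levels = cls))
  if (any(n == 0)) stop("a class is empty")
  m <- min(n)
  keep <- with_seed(seed, unlist(lapply(cls, function(cl) {
    idx <- which(fm$labels == cl)
    if (length(idx) > m) sort(sample(idx, m)) else idx
  })))
  subset_fm(fm, sort(keep))
}

#' Train a linear soft-margin SVM
#'
#' Wraps the libsvm implementation (`e1071::svm`) with a linear kernel, cost
#' `C` and optional per-class cost multipliers. Features are z-scored with
#' statistics estimated here and stored in the model, so prediction uses
#' training statistics only. Decision values are oriented so larger means
#' `positive_class`.
#'
#' @param X Trials x features matrix.
#' @param y Binary labels.
#' @param C Soft-margin cost (default 1).
#' @param class_weights Named per-class cost multipliers (default equal).
#' @param positive_class Label treated as positive; defaults to the first
#'   level encountered.
#' @return A `linear_svm` model.
#' @export
train_linear_classifier <- function(X, y, C = 1, class_weights = NULL,
                                    positive_class = NULL) {
  stopifnot(C > 0)
  y <- as.character(y)
  cls <- unique(y)
  if (length(cls) < 2) stop("training labels contain a single class")
  if (is.null(positive_class)) positive_class <- cls[1]
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  yf <- factor(y)
  fit <- e1071::svm(Xs, yf, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = class_weights)
  dv <- attr(stats::predict(fit, Xs, decision.values = TRUE),
             "decision.values")[, 1]
  flip <- if (stats::cor(dv, as.numeric(y == positive_class)) < 0) -1 else 1
  structure(list(fit = fit, mu = mu, sd = sdev, flip = flip,
                 positive_class = positive_class, classes = levels(yf)),
            class = "linear_svm")
}

#' Predict labels and decision values from a linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Trials x features matrix (raw scale; standardization uses
#'   the stored training statistics).
#' @param ... Unused.
#' @return List with `labels` and `decision` (larger = more positive-class).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  Xs <- sweep(sweep(newdata, 2, object$mu), 2, object$sd, "/")
  pr <- stats::predict(object$fit, Xs, decision.values = TRUE)
  list(labels = as.character(pr),
       decision = object$flip * attr(pr, "decision.values")[, 1])
}

# Seeded stratified fold assignment.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  })
  folds
}

#' Stratified k-fold cross-validated accuracy
#'
#' Standardization is fitted inside each training fold (by the classifier)
#' and the training fold is balanced by down-sampling before fitting, so no
#' test-fold information enters training. Accuracy is pooled over all
#' held-out trials.
#'
#' @param fm A `feature_matrix` with a binary label.
#' @param k Number of folds (default 10).
#' @param C SVM cost.
#' @param class_weights Optional per-class cost multipliers.
#' @param balance Balance each training fold (default TRUE).
#' @param seed Integer seed for folds and balancing.
#' @return List with `accuracy`, `per_fold`, `folds`.
#' @export
crossvalidate <- function(fm, k = 10, C = 1, class_weights = NULL,
                          balance = TRUE, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  cls <- unique(fm$labels)
  if (length(cls) != 2) stop("crossvalidate needs exactly 2 classes")
  if (min(table(fm$labels)) < k)
    stop("need at least k trials per class")
  folds <- stratified_folds(fm$labels, k, seed)
  correct <- logical(length(fm$labels))
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- subset_fm(fm, folds != f)
    if (balance) tr <- balance_classes(tr, seed = derive_seed(seed, f))
    model <- train_linear_classifier(tr$X, tr$labels, C = C,
                                     class_weights = class_weights)
    pred <- predict(model, fm$X[folds == f, , drop = FALSE])
    hit <- pred$labels == fm$labels[folds == f]
    correct[folds == f] <- hit
    per_fold[f] <- mean(hit)
  }
  list(accuracy = mean(correct), per_fold = per_fold, folds = folds)
}

#' Permutation-test significance threshold for CV accuracy
#'
#' For each repetition the label vector is randomly permuted before training
#' and the full cross-validation is re-run; the threshold is the empirical
#' `1 - alpha` quantile of the permuted accuracies.
#'
#' @inheritParams crossvalidate
#' @param n_perm Number of repetitions (default 1200).
#' @param alpha Significance level (default 0.05).
#' @return List with `threshold` and the vector of `permuted_accuracies`.
#' @export
permutation_threshold <- function(fm, n_perm = 1200, alpha = 0.05, k = 10,
                                  C = 1, seed = 1L) {
  if (n_perm < 20) warning("few permutations; the quantile will be unstable")
  acc <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    pm <- fm
    pm$labels <- with_seed(derive_seed(seed, r), sample(fm$labels))
    acc[r] <- crossvalidate(pm, k = k, C = C,
                            seed = derive_seed(seed, r + n_perm))$accuracy
  }
  list(threshold = as.numeric(stats::quantile(acc, 1 - alpha, type = 1)),
       permuted_accuracies = acc)
}

#' Pairwise severity classification contrasts
#'
#' Classifies execution-error trials of one severity against another for
#' every severity pair, plus the joined mirror-angle classes (45 with 315
#' degrees against 90 with 270). Pairs with too few trials for the requested
#' fold count are skipped with a message.
#'
#' @param ts A `trialset` containing execution trials with severity labels.
#' @param mode Feature mode passed to [build_feature_matrix()].
#' @param k,C,seed As in [crossvalidate()].
#' @param include_joined Include the mirror-angle joined contrast.
#' @return Data frame with columns `contrast`, `n_trials`, `accuracy`
#'   (`NA` when skipped).
#' @export
severity_contrasts <- function(ts, mode = "freq", k = 10, C = 1, seed = 1L,
                               include_joined = TRUE) {
  exec_idx <- which(ts$labels == "execution" & !is.na(ts$severity))
  if (!length(exec_idx)) stop("no execution trials with severity labels")
  ts <- subset_trialset(ts, exec_idx)
  fm <- build_feature_matrix(ts, mode = mode)
  sev <- ts$severity
  levels_present <- sort(unique(sev))
  groups <- lapply(levels_present, function(s) which(sev == s))
  names(groups) <- as.character(levels_present)
  contrasts <- if (length(levels_present) >= 2)
    utils::combn(as.character(levels_present), 2, simplify = FALSE)
  else list()
  contrasts <- lapply(contrasts, function(p)
    list(name = paste(p, collapse = "_vs_"),
         a = groups[[p[1]]], b = groups[[p[2]]]))
  if (include_joined &&
      all(c("45", "315", "90", "270") %in% names(groups)))
    contrasts <- c(contrasts, list(list(
      name = "45+315_vs_90+270",
      a = c(groups[["45"]], groups[["315"]]),
      b = c(groups[["90"]], groups[["270"]]))))
  res <- lapply(contrasts, function(ct) {
    n_a <- length(ct$a); n_b <- length(ct$b)
    if (min(n_a, n_b) < k) {
      message("severity contrast ", ct$name, " skipped: too few trials")
      return(data.frame(contrast = ct$name, n_trials = n_a + n_b,
                        accuracy = NA_real_))
    }
    sub <- subset_fm(fm, c(ct$a, ct$b))
    sub$labels <- c(rep("a", n_a), rep("b", n_b))
    cv <- crossvalidate(sub, k = k, C = C, seed = seed)
    data.frame(contrast = ct$name, n_trials = n_a + n_b,
               accuracy = cv$accuracy)
  })
  do.call(rbind, res)
}
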