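# Asynchronous sliding-window error detection.
#
# A 1-s window is shifted over the continuous signal in 62.5 ms steps; each
# window is summarized by Burg order-16 spectra (1-12 Hz, 1 Hz bins) of its
# 0.1-0.5 s sub-window on every EEG channel, reduced to the 20 strongest
# features by r-squared, classified by a (class-weighted) linear SVM, mapped
# to a probability by a Platt sigmoid, smoothed over the last three steps and
# thresholded.

#' Sliding-window start times over a recording
#'
#' Half-open 1-s windows every 62.5 ms; the step must be an integer number of
#' samples at the recording's rate (32 samples at 512 Hz).
#'
#' @param rec An `errp_recording` (or anything with `fs_Hz` and a duration).
#' @param length_s Window length (default 1).
#' @param step_s Step (default 0.0625).
#' @return List with `start_s` (window start times) and `start_idx`
#'   (0-based start samples).
#' @export
sliding_windows <- function(rec, length_s = 1, step_s = 0.0625) {
  fs <- rec$fs_Hz
  dur <- recording_duration(rec)
  if (dur < length_s) stop("recording shorter than one window")
  step_samp <- step_s * fs
  if (abs(step_samp - round(step_samp)) > 1e-9)
    stop("step must be an integer number of samples at this sampling rate")
  step_samp <- as.integer(round(step_samp))
  len_samp <- as.integer(round(length_s * fs))
  n_win <- (ncol(rec$signal) - len_samp) %/% step_samp + 1L
  start_idx <- (seq_len(n_win) - 1L) * step_samp
  list(start_s = start_idx / fs, start_idx = start_idx,
       length_samp = len_samp)
}

#' Burg spectral features for 1-s windows
#'
#' For each window start, the Burg order-16 spectrum on 1-12 Hz (1 Hz bins)
#' is computed from the 0.1-0.5 s sub-window of every EEG channel and the
#' per-channel spectra are concatenated (12 x n_eeg features).
#'
#' @param rec An `errp_recording`.
#' @param start_idx 0-based window start samples.
#' @param order Burg model order (default 16).
#' @param sub_range Sub-window in seconds relative to window start.
#' @param freq_grid_Hz Spectrum grid.
#' @return Matrix, windows x features.
#' @export
async_features <- function(rec, start_idx, order = 16,
                           sub_range = c(0.1, 0.5), freq_grid_Hz = 1:12) {
  fs <- rec$fs_Hz
  eeg_idx <- which(rec$channel_kinds == "eeg")
  rel <- sample_range(sub_range[1], sub_range[2], fs)
  n_f <- length(freq_grid_Hz)
  out <- matrix(0, length(start_idx), n_f * length(eeg_idx))
  for (w in seq_along(start_idx)) {
    seg <- t(rec$signal[eeg_idx, start_idx[w] + rel, drop = FALSE])
    sp <- burg_psd(seg, fs, order = order, freq_grid_Hz = freq_grid_Hz)
    out[w, ] <- as.numeric(sp$power)   # bin-major within channel
  }
  colnames(out) <- as.vector(outer(freq_grid_Hz, rec$channel_labels[eeg_idx],
                                   function(f, c) paste0(c, "_", f, "Hz")))
  out
}

# Same features from an event-locked trialset (training path).
trialset_async_features <- function(ts, order = 16, sub_range = c(0.1, 0.5),
                                    freq_grid_Hz = 1:12) {
  eeg_idx <- which(ts$channel_kinds == "eeg")
  rel <- sample_range(sub_range[1] - ts$window[1],
                      sub_range[2] - ts$window[1], ts$fs_Hz)
  n_tr <- dim(ts$epochs)[1]
  out <- matrix(0, n_tr, length(freq_grid_Hz) * length(eeg_idx))
  for (t in seq_len(n_tr)) {
    seg <- t(matrix(ts$epochs[t, eeg_idx, rel], nrow = length(eeg_idx)))
    sp <- burg_psd(seg, ts$fs_Hz, order = order, freq_grid_Hz = freq_grid_Hz)
    out[t, ] <- as.numeric(sp$power)
  }
  out
}

# Platt/Lin sigmoid calibration: fit (A, B) of p = 1/(1 + exp(A d + B)) by
# regularized maximum likelihood (prior-corrected targets), Newton descent
# with backtracking.
fit_platt <- function(decision, positive) {
  t1 <- sum(positive); t0 <- sum(!positive)
  hi <- (t1 + 1) / (t1 + 2); lo <- 1 / (t0 + 2)
  target <- ifelse(positive, hi, lo)
  d <- -decision        # so p increasing in decision after fit (A ends ~ +)
  A <- 0; B <- log((t0 + 1) / (t1 + 1))
  obj <- function(A, B) {
    f <- A * d + B
    sum(ifelse(f >= 0, target * f + log1p(exp(-f)),
               (target - 1) * f + log1p(exp(f))))
  }
  val <- obj(A, B)
  for (it in 1:100) {
    f <- A * d + B
    p <- 1 / (1 + exp(f))
    g <- p * (1 - p)
    d1A <- sum(d * (target - p)); d1B <- sum(target - p)
    h11 <- sum(d * d * g) + 1e-12; h22 <- sum(g) + 1e-12; h12 <- sum(d * g)
    det <- h11 * h22 - h12 * h12
    if (det <= 0) break
    dA <- -(h22 * d1A - h12 * d1B) / det
    dB <- -(h11 * d1B - h12 * d1A) / det
    step <- 1
    repeat {
      nv <- obj(A + step * dA, B + step * dB)
      if (nv < val + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    if (abs(val - nv) < 1e-10) { A <- A + step * dA; B <- B + step * dB; break }
    A <- A + step * dA; B <- B + step * dB; val <- nv
  }
  # stored in the convention p = 1/(1+exp(A d + B)) on the raw decision value
  c(A = -A, B = B)
}

platt_prob <- function(decision, ab)
  1 / (1 + exp(ab["A"] * decision + ab["B"]))

#' Train an asynchronous error detector
#'
#' From event-locked training trials (error plus no-error): score all Burg
#' spectral features by r-squared and keep the 20 strongest; fit a linear
#' SVM (`C = 1`), with the error-class cost weighted 5:1 for outcome-error
#' detectors (the much rarer class) and equal weights for execution; fit a
#' Platt sigmoid on decision values obtained by 3-fold internal
#' cross-fitting, so the calibration never sees decision values of the
#' trials a sub-model was trained on.
#'
#' @param ts Event-locked `trialset` containing trials of `error_kind` and
#'   `noError` trials.
#' @param error_kind `"execution"` or `"outcome"`.
#' @param n_features Number of selected features (default 20).
#' @param C SVM cost (default 1).
#' @param error_weight Cost multiplier for the error class; default 5 for
#'   outcome, 1 for execution.
#' @param smoothing_weights Temporal smoothing weights, oldest first;
#'   normalized to sum 1 (default `c(1, 2, 3) / 6`).
#' @param threshold Decision threshold on the smoothed probability.
#' @param seed Integer seed (balancing, internal folds).
#' @param balance Balance classes by down-sampling before fitting (used for
#'   the execution detector; the outcome detector instead keeps all trials
#'   and uses the 5:1 cost weighting).
#' @return A `detector_model`.
#' @export
train_detector <- function(ts, error_kind = c("outcome", "execution"),
                           n_features = 20, C = 1, error_weight = NULL,
                           smoothing_weights = c(1, 2, 3) / 6,
                           threshold = 0.8, seed = 1L, balance = NULL) {
  error_kind <- match.arg(error_kind)
  if (is.null(error_weight))
    error_weight <- if (error_kind == "outcome") 5 else 1
  if (is.null(balance)) balance <- error_kind == "execution"
  keep <- ts$labels %in% c(error_kind, "noError")
  ts <- subset_trialset(ts, keep)
  y <- ifelse(ts$labels == error_kind, "error", "noError")
  X <- trialset_async_features(ts)
  fm <- structure(list(X = X, labels = y, severity = ts$severity,
                       feature_names = colnames(X), mode = "freq"),
                  class = "feature_matrix")
  if (balance) fm <- balance_classes(fm, seed = derive_seed(seed, 99))
  X <- fm$X; y <- fm$labels

  r2 <- r2_scores(X, y)
  sel <- sort(select_top_features(r2, n_features))
  Xs <- X[, sel, drop = FALSE]
  cw <- c(error = error_weight, noError = 1)
  model <- train_linear_classifier(Xs, y, C = C, class_weights = cw,
                                   positive_class = "error")

  # 3-fold internal cross-fitting for unbiased calibration decision values
  folds <- stratified_folds(y, 3, derive_seed(seed, 7))
  dv <- numeric(length(y))
  for (f in 1:3) {
    sub <- train_linear_classifier(Xs[folds != f, , drop = FALSE],
                                   y[folds != f], C = C, class_weights = cw,
                                   positive_class = "error")
    dv[folds == f] <- predict(sub, Xs[folds == f, , drop = FALSE])$decision
  }
  ab <- fit_platt(dv, y == "error")

  w <- smoothing_weights / sum(smoothing_weights)
  stopifnot(length(w) == 3, all(w >= 0), threshold >= 0)
  structure(list(selected_feature_indices = sel, classifier = model,
                 calibration = ab, smoothing_weights = w,
                 threshold = threshold, error_kind = error_kind,
                 error_weight = error_weight, r2 = r2),
            class = "detector_model")
}

# Smooth a probability stream: weighted average of the last three values,
# weights renormalized over the available history at the first two steps.
smooth_probabilities <- function(p, w) {
  n <- length(p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - 2):i
    wi <- w[(3 - length(j) + 1):3]
    out[i] <- sum(wi * p[j]) / sum(wi)
  }
  out
}

#' Run a detector over a continuous recording
#'
#' Slides 1-s windows in 62.5 ms steps, computes features, applies the
#' stored feature selection, classifier and sigmoid calibration, smooths the
#' probability stream over the last three steps and thresholds it.
#'
#' @param rec Preprocessed `errp_recording`.
#' @param model A `detector_model`.
#' @param start_idx Optional restriction to specific 0-based window starts
#'   (defaults to all windows).
#' @return A `detection_trace` data frame: `time_s`, `p_raw`, `p_smooth`,
#'   `decision`.
#' @export
detect <- function(rec, model, start_idx = NULL) {
  sw <- sliding_windows(rec)
  if (is.null(start_idx)) start_idx <- sw$start_idx
  X <- async_features(rec, start_idx)
  Xs <- X[, model$selected_feature_indices, drop = FALSE]
  dv <- predict(model$classifier, Xs)$decision
  p_raw <- platt_prob(dv, model$calibration)
  p_smooth <- smooth_probabilities(p_raw, model$smoothing_weights)
  out <- data.frame(time_s = start_idx / rec$fs_Hz, p_raw = p_raw,
                    p_smooth = p_smooth,
                    decision = p_smooth > model$threshold)
  class(out) <- c("detection_trace", "data.frame")
  out
}

#' Ground-truth labels for sliding windows
#'
#' A window is positive when its start time lies within `label_window`
#' seconds after an onset of the given kind, so that the 0.1-0.5 s feature
#' sub-window overlaps the error response.
#'
#' @param start_s Window start times.
#' @param events An `errp_events` table.
#' @param error_kind Which event type defines positives.
#' @param label_window Positive range after onset (default `c(0, 0.5)`).
#' @return Logical vector.
#' @export
window_labels <- function(start_s, events, error_kind,
                          label_window = c(0, 0.5)) {
  ev <- as.data.frame(events)
  on <- ev$onset_s[ev$event_type == error_kind]
  vapply(start_s, function(t)
    any(t >= on + label_window[1] & t <= on + label_window[2]), TRUE)
}

#' Chronological k-fold cross-validation of the asynchronous detector
#'
#' The recording is split into `k` contiguous equal-length segments. For each
#' fold, a detector is trained on the event-locked trials (errors of the
#' requested kind plus no-error trials) from the other segments and run over
#' all sliding windows lying entirely inside the held-out segment, so
#' training and test data never overlap in time. Windows straddling segment
#' boundaries are excluded.
#'
#' @param rec Preprocessed `errp_recording`.
#' @param events `errp_events` table.
#' @param error_kind `"execution"` or `"outcome"`.
#' @param k Number of segments (default 10).
#' @param seed Integer seed.
#' @param threshold Decision threshold stored in each fold's detector.
#' @param max_noerror_per_fold Cap on no-error training trials per fold.
#' @return List with `trace` (pooled `detection_trace` plus a `fold` column,
#'   ordered by time), `labels` (per-window ground truth) and `folds_without_errors`.
#' @export
chrono_crossvalidate <- function(rec, events, error_kind = "execution",
                                 k = 10, seed = 1L, threshold = 0.8,
                                 max_noerror_per_fold = 400) {
  dur <- recording_duration(rec)
  seg_len <- dur / k
  ev <- as.data.frame(events)
  trialset_all <- build_trialset(rec, events)
  sw <- sliding_windows(rec)

  traces <- list()
  labels <- list()
  empty_folds <- integer(0)
  for (f in seq_len(k)) {
    lo_seg <- (f - 1) * seg_len
    hi_seg <- f * seg_len
    # training trials must be temporally disjoint from the test segment
    disjoint <- (trialset_all$onsets + diff(trialset_all$window)) <= lo_seg |
      trialset_all$onsets >= hi_seg
    tr_idx <- which(disjoint &
                      trialset_all$labels %in% c(error_kind, "noError"))
    tr <- subset_trialset(trialset_all, tr_idx)
    # cap no-error trials to keep training sets manageable
    ne <- which(tr$labels == "noError")
    if (length(ne) > max_noerror_per_fold) {
      drop <- with_seed(derive_seed(seed, 1000 + f),
                        sample(ne, length(ne) - max_noerror_per_fold))
      tr <- subset_trialset(tr, setdiff(seq_along(tr$labels), drop))
    }
    if (!any(tr$labels == error_kind)) {
      empty_folds <- c(empty_folds, f)
      next
    }
    model <- train_detector(tr, error_kind, threshold = threshold,
                            seed = derive_seed(seed, f))
    in_seg <- sw$start_s >= lo_seg & (sw$start_s + 1) <= hi_seg + 1e-9
    if (!any(in_seg)) next
    trace <- detect(rec, model, start_idx = sw$start_idx[in_seg])
    trace$fold <- f
    traces[[length(traces) + 1]] <- trace
    labels[[length(labels) + 1]] <-
      window_labels(trace$time_s, events, error_kind)
    test_has_error <- any(window_labels(trace$time_s, events, error_kind))
    if (!test_has_error)
      message("fold ", f, " has no ", error_kind,
              " event; evaluated for specificity only")
  }
  trace <- do.call(rbind, traces)
  lab <- unlist(labels)
  ord <- order(trace$time_s)
  list(trace = trace[ord, ], labels = lab[ord],
       folds_without_errors = empty_folds)
}
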