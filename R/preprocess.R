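# Signal conditioning: band-pass + notch filtering, EOG artifact regression,
# common-average referencing, and segmentation into labelled trials.
#
# The canonical order is filter -> EOG regression -> CAR -> segmentation; a
# provenance flag on the recording records which stages have run.

mark_stage <- function(rec, stage) {
  rec$metadata$pipeline <- c(rec$metadata$pipeline %||% character(0), stage)
  rec
}

#' Band-pass and notch filter a recording
#'
#' Butterworth band-pass (default 0.5-60 Hz, order 4) plus a band-stop notch
#' around the power-line frequency (default 50 Hz). Offline analysis uses
#' zero-phase forward-backward application; the asynchronous detector can
#' request causal (single-pass) filtering to honour real-time constraints.
#'
#' @param rec An `errp_recording`.
#' @param band Pass-band edges in Hz.
#' @param notch Notch centre frequency in Hz (`NULL` to skip).
#' @param causal If `TRUE`, single-pass filtering; default zero-phase.
#' @return Filtered recording (stick channels are left untouched).
#' @export
filter_signal <- function(rec, band = c(0.5, 60), notch = 50,
                          causal = FALSE) {
  stopifnot(inherits(rec, "errp_recording"))
  fs <- rec$fs_Hz
  if (band[1] >= band[2]) stop("band edges inverted")
  if (band[1] <= 0 || band[2] >= fs / 2) stop("band must lie inside (0, fs/2)")
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  nf <- if (!is.null(notch))
    signal::butter(2, c(notch - 2, notch + 2) / (fs / 2), type = "stop")
  apply_filt <- function(x) {
    y <- if (causal) signal::filter(bp, x) else signal::filtfilt(bp, x)
    if (!is.null(notch))
      y <- if (causal) signal::filter(nf, y) else signal::filtfilt(nf, y)
    as.numeric(y)
  }
  out <- rec
  for (c in which(rec$channel_kinds != "stick"))
    out$signal[c, ] <- apply_filt(rec$signal[c, ])
  mark_stage(out, if (causal) "filter_causal" else "filter")
}

#' Fit the EOG-to-EEG regression model
#'
#' Least-squares regression of every EEG channel on the EOG channels:
#' coefficients = inverse(EOG auto-covariance) x cross-covariance(EOG, EEG).
#' A ridge term is added (with a warning) when the EOG covariance is
#' near-singular.
#'
#' @param rec A filtered `errp_recording` with at least one EOG channel.
#' @return An `eog_model` with the `eog x eeg` coefficient matrix.
#' @export
fit_eog_regression <- function(rec) {
  stopifnot(inherits(rec, "errp_recording"))
  eog <- rec$signal[rec$channel_kinds == "eog", , drop = FALSE]
  eeg <- rec$signal[rec$channel_kinds == "eeg", , drop = FALSE]
  if (nrow(eog) < 1) stop("no EOG channels present")
  C_ee <- stats::cov(t(eog))
  C_cross <- stats::cov(t(eog), t(eeg))
  if (rcond(C_ee) < 1e-10) {
    warning("EOG covariance near-singular; using ridge-regularized solve")
    C_ee <- C_ee + diag(1e-6 * mean(diag(C_ee)) + 1e-12, nrow(C_ee))
  }
  coef <- solve(C_ee, C_cross)
  rownames(coef) <- rec$channel_labels[rec$channel_kinds == "eog"]
  colnames(coef) <- rec$channel_labels[rec$channel_kinds == "eeg"]
  structure(list(coefficients = coef), class = "eog_model")
}

#' Subtract the EOG contribution from the EEG channels
#'
#' EOG channels themselves are retained unmodified so that the confound
#' analysis can classify on them later.
#'
#' @param rec An `errp_recording`.
#' @param model An `eog_model` from [fit_eog_regression()].
#' @return Corrected recording.
#' @export
apply_eog_regression <- function(rec, model) {
  stopifnot(inherits(model, "eog_model"))
  eog <- rec$signal[rec$channel_kinds == "eog", , drop = FALSE]
  eeg_idx <- which(rec$channel_kinds == "eeg")
  rec$signal[eeg_idx, ] <- rec$signal[eeg_idx, ] -
    t(model$coefficients) %*% eog
  mark_stage(rec, "eog_regression")
}

#' Re-reference the EEG channels to their common average
#'
#' At every sample the mean across EEG channels is subtracted from each EEG
#' channel; EOG and thumbstick channels are excluded from both the mean and
#' the subtraction.
#'
#' @param rec An `errp_recording` with at least 2 EEG channels.
#' @return Re-referenced recording.
#' @export
common_average <- function(rec) {
  eeg_idx <- which(rec$channel_kinds == "eeg")
  if (length(eeg_idx) < 2) stop("common average needs at least 2 EEG channels")
  m <- colMeans(rec$signal[eeg_idx, , drop = FALSE])
  rec$signal[eeg_idx, ] <- sweep(rec$signal[eeg_idx, , drop = FALSE], 2, m)
  mark_stage(rec, "car")
}

#' Run the full conditioning chain
#'
#' Convenience wrapper: [filter_signal()] then [fit_eog_regression()] /
#' [apply_eog_regression()] then [common_average()].
#'
#' @inheritParams filter_signal
#' @return Preprocessed recording.
#' @export
preprocess_recording <- function(rec, band = c(0.5, 60), notch = 50,
                                 causal = FALSE) {
  rec <- filter_signal(rec, band, notch, causal)
  rec <- apply_eog_regression(rec, fit_eog_regression(rec))
  common_average(rec)
}

#' Segment a preprocessed recording into labelled 1-s trials
#'
#' Error trials are time-locked to event onsets. Candidate no-error windows
#' tile the recording on a 1-s grid and are kept only if the window plus a
#' 1-s guard on each side contains no event activity — where an execution
#' error is active throughout its whole perturbation interval, not just at
#' onset.
#'
#' @param rec A preprocessed `errp_recording`.
#' @param events An `errp_events` table.
#' @param trial_len_s Trial length (default 1 s).
#' @param guard_s Guard zone on each side of a no-error window (default 1 s).
#' @param max_noerror Optional cap on the number of no-error trials (earliest
#'   kept; `NULL` keeps all).
#' @return A `trialset` with labels in `execution`, `outcome`, `noError`.
#' @export
build_trialset <- function(rec, events, trial_len_s = 1, guard_s = 1,
                           max_noerror = NULL) {
  dur <- recording_duration(rec)
  ev <- as.data.frame(events)
  # active intervals: [onset, onset + duration) for perturbations, the onset
  # point itself for point events (outcome duration = 0)
  act_lo <- ev$onset_s
  act_hi <- ev$onset_s + ev$duration_s
  point <- ev$duration_s <= 0
  grid <- seq(0, floor(dur - trial_len_s), by = trial_len_s)
  keep <- vapply(grid, function(g) {
    lo <- g - guard_s; hi <- g + trial_len_s + guard_s
    hit <- (!point & act_hi > lo & act_lo < hi) |
           (point & act_lo >= lo & act_lo < hi)
    !any(hit)
  }, TRUE)
  noerr_on <- grid[keep]
  if (!is.null(max_noerror) && length(noerr_on) > max_noerror)
    noerr_on <- noerr_on[seq_len(max_noerror)]

  err_ts <- extract_epochs(rec, events, window = c(0, trial_len_s))
  ne_events <- event_table(noerr_on, rep(0, length(noerr_on)),
                           rep("outcome", length(noerr_on)))
  ne_ts <- extract_epochs(rec, ne_events, window = c(0, trial_len_s))
  ne_ts$labels <- rep("noError", length(ne_ts$labels))
  ne_ts$severity <- rep(NA_real_, length(ne_ts$labels))
  bind_trialsets(err_ts, ne_ts)
}
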