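# Performance evaluation: threshold-sweep ROC/AUC, positive/negative seconds
# rates, event-related-potential difference statistics, and aggregation of
# per-subject report tables.

#' ROC curve and AUC by threshold sweep
#'
#' Sensitivity and specificity are computed for thresholds 0 to 1 in 0.01
#' steps on the (smoothed) probability stream; the curve is anchored at
#' (0,0) and (1,1) and the AUC is the trapezoid area over
#' (1 - specificity, sensitivity). On any trace this agrees with the
#' Mann-Whitney rank statistic up to threshold quantization (< 0.01).
#'
#' @param p Probabilities in `[0, 1]`.
#' @param labels Logical (or 0/1) window labels; both classes must occur.
#' @param thresholds Sweep grid (default `seq(0, 1, 0.01)`).
#' @return List with `curve` (data frame `threshold`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @export
roc_auc <- function(p, labels, thresholds = seq(0, 1, by = 0.01)) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present for ROC analysis")
  pos <- p[labels]; neg <- p[!labels]
  sens <- vapply(thresholds, function(th) mean(pos > th), 0)
  spec <- vapply(thresholds, function(th) mean(neg <= th), 0)
  fpr <- c(0, rev(1 - spec), 1)
  tpr <- c(0, rev(sens), 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thresholds, sensitivity = sens,
                          specificity = spec),
       auc = auc)
}

#' Positive and negative seconds rates
#'
#' The timeline is partitioned into 1-s bins anchored at t = 0. A bin is
#' positive when any error's label interval (onset plus `label_window`)
#' intersects it. PSR is the fraction of positive bins containing at least
#' one above-threshold decision; NSR is the fraction of negative bins
#' containing none. Both are returned as percentages.
#'
#' @param trace A `detection_trace` (columns `time_s`, `p_smooth`).
#' @param events An `errp_events` table (or `NULL` with explicit
#'   `positive_bins`).
#' @param threshold Decision threshold (default 0.8).
#' @param error_kind Event type defining positives (`NULL`: all events).
#' @param label_window Error label interval after onset (default `c(0, 0.5)`).
#' @param duration_s Timeline length; defaults to covering the trace.
#' @return List with `psr`, `nsr` (percent), and the bin bookkeeping.
#' @export
psr_nsr <- function(trace, events, threshold = 0.8, error_kind = NULL,
                    label_window = c(0, 0.5), duration_s = NULL) {
  if (is.null(duration_s)) duration_s <- max(trace$time_s) + 1
  n_bins <- floor(duration_s)
  bins <- seq_len(n_bins) - 1             # bin b covers [b, b+1)
  ev <- as.data.frame(events)
  if (!is.null(error_kind)) ev <- ev[ev$event_type == error_kind, , drop = FALSE]
  lo <- ev$onset_s + label_window[1]
  hi <- ev$onset_s + label_window[2]
  positive_bin <- vapply(bins, function(b) any(lo < b + 1 & hi >= b), TRUE)
  det_t <- trace$time_s[trace$p_smooth > threshold]
  det_bin <- vapply(bins, function(b) any(det_t >= b & det_t < b + 1), TRUE)
  psr <- if (any(positive_bin)) 100 * mean(det_bin[positive_bin]) else NA_real_
  nsr <- if (any(!positive_bin)) 100 * mean(!det_bin[!positive_bin]) else NA_real_
  list(psr = psr, nsr = nsr, positive_bins = bins[positive_bin],
       detected_bins = bins[det_bin], n_bins = n_bins)
}

#' Pointwise ERP difference statistics between two trial groups
#'
#' At one channel, the two groups' epochs are compared sample by sample with
#' Welch's unequal-variance two-sample t-test; p-values are Bonferroni
#' corrected over the number of time samples tested, contiguous significant
#' samples are merged into intervals, and the latency of the largest
#' absolute difference within each interval is reported.
#'
#' @param ts_a,ts_b `trialset`s with identical epoch geometry (>= 2 trials
#'   each).
#' @param channel Channel label at which to test (default `"FCz"`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return List with `difference` (mean waveform a - b), `time_s`,
#'   `p_values`, `significant` (logical per sample), `intervals` (data frame
#'   `start_s`, `end_s`, `peak_latency_s`, `peak_uV`).
#' @export
erp_difference_stats <- function(ts_a, ts_b, channel = "FCz", alpha = 0.05) {
  stopifnot(identical(dim(ts_a$epochs)[3], dim(ts_b$epochs)[3]),
            ts_a$fs_Hz == ts_b$fs_Hz)
  if (dim(ts_a$epochs)[1] < 2 || dim(ts_b$epochs)[1] < 2)
    stop("need at least 2 trials per group")
  ci <- match(channel, ts_a$channel_labels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  A <- ts_a$epochs[, ci, , drop = TRUE]
  B <- ts_b$epochs[, ci, , drop = TRUE]
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  pvals <- 2 * stats::pt(-abs(tstat), df)
  n_samp <- length(pvals)
  sig <- pvals < alpha / n_samp
  t_axis <- ts_a$window[1] + (seq_len(n_samp) - 1) / ts_a$fs_Hz
  diffw <- ma - mb

  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  iv <- which(runs$values)
  intervals <- do.call(rbind, lapply(iv, function(i) {
    idx <- starts[i]:ends[i]
    pk <- idx[which.max(abs(diffw[idx]))]
    data.frame(start_s = t_axis[starts[i]], end_s = t_axis[ends[i]],
               peak_latency_s = t_axis[pk], peak_uV = diffw[pk])
  }))
  if (is.null(intervals))
    intervals <- data.frame(start_s = numeric(0), end_s = numeric(0),
                            peak_latency_s = numeric(0), peak_uV = numeric(0))
  list(difference = diffw, time_s = t_axis, p_values = pvals,
       significant = sig, intervals = intervals)
}

#' Aggregate per-subject performance reports
#'
#' Arithmetic mean of every shared numeric metric across reports (rows), the
#' way multi-subject result tables report their "Mean" row. Storage keeps
#' full precision; use `digits` for display rounding only.
#'
#' @param reports Data frame with one row per subject/session and one column
#'   per metric (non-numeric columns are ignored), or a list of named
#'   numeric vectors with identical names.
#' @param digits Optional rounding for the returned means.
#' @return Named numeric vector of metric means.
#' @export
aggregate_report <- function(reports, digits = NULL) {
  if (is.list(reports) && !is.data.frame(reports)) {
    nms <- lapply(reports, names)
    if (length(unique(vapply(nms, paste, "", collapse = "|"))) != 1)
      stop("inconsistent metric sets across reports")
    reports <- as.data.frame(do.call(rbind, reports))
  }
  num <- vapply(reports, is.numeric, TRUE)
  if (!any(num)) stop("no numeric metrics to aggregate")
  m <- colMeans(reports[, num, drop = FALSE])
  if (!is.null(digits)) m <- round(m, digits)
  m
}

#' Reference subject-level results bundled with the package
#'
#' Per-subject event-locked classification accuracies and asynchronous
#' detection performance (AUC, PSR, NSR at threshold 0.8) from the original
#' ten-subject continuous-feedback study this pipeline replicates; used to
#' validate the aggregation routines against the published group means.
#'
#' @param which `"event_locked"` or `"async"`.
#' @return Data frame, one row per subject.
#' @export
reference_results <- function(which = c("event_locked", "async")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("reference_", which, if (which == "async")
                     "_performance.tsv" else "_accuracies.tsv"),
                   package = "errpdetect")
  utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE)
}
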