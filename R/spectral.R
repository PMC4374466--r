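# Power-spectrum estimators and class-contrast feature scores.
#
# Two estimators are used in the pipeline: Welch's averaged modified
# periodogram (event-locked frequency features, band-power checks) and the
# Burg maximum-entropy method (asynchronous detector features, order 16 on
# 1-12 Hz at 1 Hz bins).

#' Welch power spectral density
#'
#' Averaged modified periodograms with a Hann taper and one-sided density
#' scaling, so the integral of the density over frequency recovers the signal
#' variance (Parseval). With the defaults (segment 256, overlap 128, FFT 512)
#' at 512 Hz the bins are 1 Hz apart, and the "first 40 bins" used as
#' event-locked features span 0-39 Hz.
#'
#' @param x Numeric vector, or matrix with one series per column.
#' @param fs_Hz Sampling rate.
#' @param segment_len Samples per segment (default 256).
#' @param overlap Overlapping samples between segments (default 128).
#' @param fft_len FFT length, >= `segment_len` (default 512).
#' @return List with `freq_Hz` and `power` (matrix, frequencies x series;
#'   dropped to a vector for vector input).
#' @export
welch_psd <- function(x, fs_Hz, segment_len = 256, overlap = 128,
                      fft_len = 512) {
  vec_in <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(fft_len >= segment_len, overlap < segment_len)
  if (n < segment_len) {
    warning("segment shorter than one Welch segment; using a single periodogram")
    segment_len <- n
    overlap <- 0
  }
  step <- segment_len - overlap
  starts <- seq(1, n - segment_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(segment_len) - 1) / (segment_len - 1))
  scale <- 1 / (fs_Hz * sum(w^2))
  n_keep <- fft_len %/% 2 + 1
  acc <- matrix(0, n_keep, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + segment_len - 1), , drop = FALSE] * w
    if (fft_len > segment_len)
      seg <- rbind(seg, matrix(0, fft_len - segment_len, ncol(seg)))
    P <- abs(stats::mvfft(seg))^2 * scale
    acc <- acc + P[seq_len(n_keep), , drop = FALSE]
  }
  acc <- acc / length(starts)
  # one-sided: double everything except DC and Nyquist
  dbl <- seq_len(n_keep) != 1 & seq_len(n_keep) != n_keep
  acc[dbl, ] <- 2 * acc[dbl, ]
  freq <- (seq_len(n_keep) - 1) * fs_Hz / fft_len
  list(freq_Hz = freq, power = if (vec_in) drop(acc) else acc)
}

#' Burg (maximum-entropy) power spectral density
#'
#' Fits an autoregressive model of the given order by Burg's recursion
#' (minimizing the summed forward and backward prediction error; reflection
#' coefficients bounded by 1) and evaluates the one-sided AR spectrum on a
#' frequency grid. A constant segment returns a flat epsilon spectrum rather
#' than failing.
#'
#' @param x Numeric vector, or matrix with one series per column.
#' @param fs_Hz Sampling rate.
#' @param order AR model order (default 16).
#' @param freq_grid_Hz Evaluation frequencies (default 1-12 Hz step 1).
#' @return List with `freq_Hz`, `power` (frequencies x series), `phi` (AR
#'   coefficients, order x series) and `var_pred`.
#' @export
burg_psd <- function(x, fs_Hz, order = 16, freq_grid_Hz = 1:12) {
  vec_in <- is.null(dim(x))
  x <- as.matrix(x)
  if (order >= nrow(x)) stop("model order must be below the segment length")
  if (any(freq_grid_Hz <= 0) || any(freq_grid_Hz >= fs_Hz / 2))
    stop("freq_grid must lie inside (0, fs/2)")
  fit <- burg_ar_cpp(x, as.integer(order))
  power <- ar_spectrum(fit$phi, fit$var_pred, fs_Hz, freq_grid_Hz)
  list(freq_Hz = freq_grid_Hz,
       power = if (vec_in) drop(power) else power,
       phi = fit$phi, var_pred = fit$var_pred)
}

#' One-sided spectrum of an AR process
#'
#' Closed form `S(f) = 2 sigma^2 / (fs |1 - sum_k phi_k e^{-2pi i f k / fs}|^2)`
#' for coefficients in the convention `x[t] = sum_k phi_k x[t-k] + e[t]`.
#' Also serves as the analytic oracle for known-coefficient processes.
#'
#' @param phi AR coefficients (vector, or order x series matrix).
#' @param var_pred Innovation variance(s).
#' @param fs_Hz Sampling rate.
#' @param freq_Hz Evaluation frequencies.
#' @return Matrix, frequencies x series.
#' @export
ar_spectrum <- function(phi, var_pred, fs_Hz, freq_Hz) {
  phi <- as.matrix(phi)
  p <- nrow(phi)
  E <- exp(-2i * pi * outer(freq_Hz, seq_len(p)) / fs_Hz)  # freq x order
  denom <- abs(1 - E %*% phi)^2                            # freq x series
  sweep(1 / denom, 2, 2 * var_pred / fs_Hz, `*`)
}

#' Squared point-biserial correlation per feature
#'
#' The class-contrast score used for feature selection and band maps: for a
#' binary label, the squared Pearson correlation between each feature column
#' and the 0/1 label. Zero-variance features score 0.
#'
#' @param features Matrix, trials x features.
#' @param labels Binary labels (factor, character or 0/1), >= 2 per class.
#' @return Numeric vector of r-squared values in `[0, 1]`.
#' @export
r2_scores <- function(features, labels) {
  features <- as.matrix(features)
  y <- as.numeric(factor(labels))
  if (length(unique(y)) != 2) stop("labels must have exactly 2 classes")
  if (min(table(y)) < 2) stop("need at least 2 trials per class")
  y <- y - mean(y)
  Xc <- sweep(features, 2, colMeans(features))
  num <- as.numeric(crossprod(Xc, y))^2
  den <- colSums(Xc^2) * sum(y^2)
  r2 <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r2, 0), 1)
}

#' Select the indices of the strongest features by r-squared
#'
#' Ties are broken by lower feature index, so selection is deterministic.
#'
#' @param r2 Vector of scores.
#' @param n_keep Number of features to keep (default 20). If fewer features
#'   exist, all are kept with a warning.
#' @return Integer vector of selected indices (ascending score rank).
#' @export
select_top_features <- function(r2, n_keep = 20) {
  if (length(r2) < n_keep) {
    warning("fewer features than requested; keeping all")
    return(seq_along(r2))
  }
  order(-r2, seq_along(r2))[seq_len(n_keep)]
}
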