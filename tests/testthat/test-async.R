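test_that("sliding-window bookkeeping matches the 62.5 ms step arithmetic", {
  rec10 <- recording(matrix(0, 1, 512 * 10), 512, "Cz", "eeg")
  sw <- sliding_windows(rec10)
  expect_equal(length(sw$start_s), 145)
  expect_equal(diff(sw$start_s[1:2]), 0.0625)
  rec1 <- recording(matrix(0, 1, 512), 512, "Cz", "eeg")
  expect_equal(length(sliding_windows(rec1)$start_s), 1)
  expect_error(sliding_windows(rec10, step_s = 0.03), "integer number")
  expect_error(sliding_windows(rec1, length_s = 2), "shorter")
})

test_that("asynchronous features are 12 bins per EEG channel from the 0.1-0.5 s sub-window", {
  sess <- cached_session(10, seed = 5)
  rec <- sess$preprocessed
  X <- async_features(rec, start_idx = c(0L, 512L))
  expect_equal(dim(X), c(2, 12 * 28))
  # all-zero window gives the epsilon-flat floor
  zrec <- recording(matrix(0, 2, 512 * 2), 512, c("Cz", "Fz"),
                    c("eeg", "eeg"))
  Xz <- async_features(zrec, start_idx = 0L)
  expect_true(all(Xz < 1e-12) && all(is.finite(Xz)))
  # a theta burst confined to 0.2-0.4 s of the window raises the 5-7 Hz bins
  fs <- 512
  set.seed(2)
  base <- matrix(rnorm(2 * fs * 2), 2)
  burst <- sin(2 * pi * 6 * (0:(0.2 * fs - 1)) / fs) * 8
  with_b <- base
  with_b[1, sample_range(0.2, 0.4, fs)] <- with_b[1, sample_range(0.2, 0.4, fs)] + burst
  r_no <- recording(base, fs, c("Cz", "Fz"), c("eeg", "eeg"))
  r_b <- recording(with_b, fs, c("Cz", "Fz"), c("eeg", "eeg"))
  theta_cols <- 5:7          # Cz is channel 1: bins 1-12 are its spectrum
  expect_gt(mean(async_features(r_b, 0L)[1, theta_cols]),
            3 * mean(async_features(r_no, 0L)[1, theta_cols]))
})

test_that("detector training stores the documented weighting, selection and calibration", {
  sess <- cached_session(600, snr_scale = 2, seed = 23)
  ts <- build_trialset(sess$preprocessed, sess$events, max_noerror = 150)
  m_out <- train_detector(ts, "outcome", seed = 1)
  expect_equal(m_out$error_weight, 5)
  expect_equal(length(m_out$selected_feature_indices), 20)
  expect_true(all(m_out$smoothing_weights >= 0))
  expect_equal(sum(m_out$smoothing_weights), 1)
  m_ex <- train_detector(ts, "execution", seed = 1)
  expect_equal(m_ex$error_weight, 1)
})

test_that("sigmoid calibration is symmetric on symmetric data and monotone in the decision value", {
  set.seed(4)
  d <- c(rnorm(200, -2), rnorm(200, 2))
  pos <- rep(c(FALSE, TRUE), each = 200)
  ab <- errpdetect:::fit_platt(d, pos)
  p0 <- errpdetect:::platt_prob(0, ab)
  expect_lt(abs(unname(p0) - 0.5), 0.05)
  ps <- errpdetect:::platt_prob(seq(-3, 3, 0.5), ab)
  expect_true(all(diff(ps) > 0))
  expect_gt(errpdetect:::platt_prob(2, ab), 0.8)
  expect_lt(errpdetect:::platt_prob(-2, ab), 0.2)
})

test_that("probability smoothing is the documented weighted average with renormalized history", {
  w <- c(1, 2, 3) / 6
  p <- c(0, 0, 1, 1, 1)
  s <- errpdetect:::smooth_probabilities(p, w)
  expect_equal(s[1], 0)                         # only w3 available
  expect_equal(s[2], 0)                         # (w2*0 + w3*0)/(w2+w3)
  expect_equal(s[3], w[3])                      # (0,0,1) -> w3
  expect_equal(s[5], 1)                         # constant stream passes through
  # convexity: smoothed stream stays inside the raw range
  set.seed(1)
  pr <- runif(50)
  sm <- errpdetect:::smooth_probabilities(pr, w)
  expect_true(all(sm >= min(pr) - 1e-12 & sm <= max(pr) + 1e-12))
})

test_that("detection traces are well-formed and respect impossible thresholds", {
  sess <- cached_session(600, snr_scale = 2, seed = 23)
  ts <- build_trialset(sess$preprocessed, sess$events, max_noerror = 150)
  model <- train_detector(ts, "execution", seed = 1, threshold = 1.01)
  sw <- sliding_windows(sess$preprocessed)
  trace <- detect(sess$preprocessed, model, start_idx = sw$start_idx[1:200])
  expect_true(all(trace$p_raw >= 0 & trace$p_raw <= 1))
  expect_true(all(trace$p_smooth >= 0 & trace$p_smooth <= 1))
  expect_false(any(trace$decision))             # threshold above 1
  expect_equal(diff(trace$time_s[1:2]), 0.0625)
})

test_that("chronological cross-validation keeps training and test temporally disjoint", {
  sess <- cached_session(600, snr_scale = 2, seed = 23)
  ccv <- chrono_crossvalidate(sess$preprocessed, sess$events, "execution",
                              k = 5, seed = 2)
  seg_len <- 600 / 5
  expect_equal(length(ccv$labels), nrow(ccv$trace))
  # every scored window lies entirely inside its fold's segment
  lo <- (ccv$trace$fold - 1) * seg_len
  expect_true(all(ccv$trace$time_s >= lo))
  expect_true(all(ccv$trace$time_s + 1 <= lo + seg_len + 1e-9))
  # a detector trained with signal present beats chance on held-out segments
  expect_gt(roc_auc(ccv$trace$p_smooth, ccv$labels)$auc, 0.7)
})

test_that("detection performance is monotone in injection strength and null at zero", {
  aucs <- sapply(c(0, 1, 2), function(snr) {
    sess <- cached_session(300, snr_scale = snr, seed = 61)
    ccv <- chrono_crossvalidate(sess$preprocessed, sess$events,
                                "execution", k = 4, seed = 5,
                                max_noerror_per_fold = 120)
    roc_auc(ccv$trace$p_smooth, ccv$labels)$auc
  })
  expect_true(all(diff(aucs) > -0.05))
  expect_gt(aucs[1], 0.40)
  expect_lt(aucs[1], 0.60)
  expect_gt(aucs[3], aucs[1] + 0.1)
})
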