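test_that("threshold-sweep AUC matches rank-statistic oracles on fixed cases", {
  # perfectly separated
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc,
               1.0, tolerance = 1e-9)
  # 4-pair hand-enumerated case: 3 of 4 rank pairs won
  r <- roc_auc(c(0.9, 0.6, 0.8, 0.3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75, tolerance = 0.01)
  # shuffled labels: near 0.5
  set.seed(5)
  p <- runif(400)
  expect_equal(roc_auc(p, sample(rep(c(TRUE, FALSE), 200)))$auc, 0.5,
               tolerance = 0.1)
  expect_error(roc_auc(p, rep(TRUE, 400)), "both classes")
})

test_that("sweep AUC equals the Mann-Whitney statistic within quantization on random traces", {
  set.seed(99)
  for (i in 1:25) {
    n1 <- sample(10:60, 1); n0 <- sample(20:120, 1)
    p <- c(plogis(rnorm(n1, 1)), plogis(rnorm(n0, -0.2)))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(roc_auc(p, lab)$auc, rank_auc(p, lab), tolerance = 0.01)
  }
})

test_that("sweep AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  p <- plogis(c(rnorm(80, 0.8), rnorm(120, -0.5)))
  lab <- rep(c(1, 0), c(80, 120))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, p, quiet = TRUE)))
  expect_equal(roc_auc(p, lab)$auc, ref, tolerance = 0.01)
})

test_that("seconds rates reproduce hand-enumerated toy traces and the trivial extremes", {
  # 10-s timeline, errors in bins 2 and 7, detections in bins 2 and 5
  trace <- data.frame(time_s = c(2.1, 5.4), p_smooth = c(0.9, 0.9))
  ev <- event_table(c(2.2, 7.3), c(0, 0), c("outcome", "outcome"))
  pn <- psr_nsr(trace, ev, threshold = 0.8, duration_s = 10)
  expect_equal(pn$psr, 50)
  expect_equal(pn$nsr, 87.5)

  # all decisions positive / negative
  t_all <- data.frame(time_s = seq(0, 9.5, 0.5), p_smooth = 1)
  expect_equal(psr_nsr(t_all, ev, 0.8, duration_s = 10)$psr, 100)
  expect_equal(psr_nsr(t_all, ev, 0.8, duration_s = 10)$nsr, 0)
  t_none <- transform(t_all, p_smooth = 0)
  expect_equal(psr_nsr(t_none, ev, 0.8, duration_s = 10)$psr, 0)
  expect_equal(psr_nsr(t_none, ev, 0.8, duration_s = 10)$nsr, 100)
})

test_that("PSR falls and NSR rises as the threshold increases", {
  set.seed(3)
  trace <- data.frame(time_s = seq(0, by = 0.0625, length.out = 1904),
                      p_smooth = runif(1904))
  ev <- event_table(seq(5, 115, 10), rep(0, 12), rep("outcome", 12))
  ths <- c(0.2, 0.5, 0.8)
  res <- sapply(ths, function(th) {
    pn <- psr_nsr(trace, ev, th, duration_s = 120)
    c(pn$psr, pn$nsr)
  })
  expect_true(all(diff(res[1, ]) <= 0))
  expect_true(all(diff(res[2, ]) >= 0))
})

test_that("pointwise difference tests are calibrated under the null and recover injected effects", {
  fs <- 128
  make_ts <- function(n, shift = 0) {
    ep <- array(rnorm(n * 1 * fs), c(n, 1, fs))
    if (shift != 0) {
      idx <- errpdetect:::sample_range(0.3, 0.5, fs)
      ep[, 1, idx] <- ep[, 1, idx] + shift
    }
    structure(list(epochs = ep, labels = rep("a", n),
                   severity = rep(NA_real_, n), window = c(0, 1), fs_Hz = fs,
                   onsets = seq_len(n), channel_labels = "FCz",
                   channel_kinds = "eeg"), class = "trialset")
  }
  # null: family-wise error controlled at alpha after Bonferroni
  set.seed(42)
  any_sig <- replicate(60, {
    s <- erp_difference_stats(make_ts(25), make_ts(25))
    any(s$significant)
  })
  expect_lte(mean(any_sig), 0.1)

  # injected offset recovered with the peak inside the significant interval
  set.seed(43)
  s <- erp_difference_stats(make_ts(200, shift = 1.5), make_ts(200))
  expect_gt(nrow(s$intervals), 0)
  expect_true(any(s$intervals$start_s <= 0.4 & s$intervals$end_s >= 0.4))

  # alpha = 0 can never flag anything
  s0 <- erp_difference_stats(make_ts(200, shift = 1.5), make_ts(200),
                             alpha = 0)
  expect_equal(nrow(s0$intervals), 0)
  expect_error(erp_difference_stats(make_ts(1), make_ts(5)), "2 trials")
})

test_that("report aggregation means metrics and rejects inconsistent inputs", {
  r <- data.frame(auc = c(0.6, 0.8), psr = c(40, 60))
  expect_equal(aggregate_report(r), c(auc = 0.7, psr = 50))
  expect_equal(aggregate_report(r[1, ]), c(auc = 0.6, psr = 40))
  expect_equal(aggregate_report(do.call(rbind, replicate(10, r[1, ],
                                                         simplify = FALSE))),
               c(auc = 0.6, psr = 40))
  expect_error(aggregate_report(list(c(a = 1), c(b = 2))), "inconsistent")
})
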