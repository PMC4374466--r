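test_that("template construction validates inputs and evaluates correctly", {
  expect_error(make_errp_template("typo", data.frame(
    latency_s = 0.3, amplitude_uV = 1, width_s = 0.05, sign = 1)),
    "unknown")
  expect_error(make_errp_template("execution", data.frame(
    latency_s = 0.3, amplitude_uV = 1, width_s = -0.05, sign = 1)),
    "width")
  expect_error(make_errp_template("execution", data.frame(
    latency_s = 1.2, amplitude_uV = 1, width_s = 0.05, sign = 1)),
    "latencies")

  # zero amplitudes give an all-zero waveform
  tz <- make_errp_template("execution", data.frame(
    latency_s = c(0.2, 0.4), amplitude_uV = c(0, 0),
    width_s = c(0.05, 0.05), sign = c(1, -1)))
  expect_equal(max(abs(evaluate_template(tz, 512))), 0)

  # single Gaussian bump peaks at its latency (within one sample)
  t1 <- make_errp_template("execution", data.frame(
    latency_s = 0.3, amplitude_uV = 1, width_s = 0.05, sign = 1))
  fcz <- match("FCz", default_montage()[1:28])
  w <- evaluate_template(t1, 512)[fcz, ]
  expect_lt(abs((which.max(abs(w)) - 1) / 512 - 0.3), 1.5 / 512)
})

test_that("default execution template has its four extrema at the stated latencies and signs", {
  fs <- 512
  fcz <- match("FCz", default_montage()[1:28])
  w <- evaluate_template(execution_template(), fs)[fcz, ]
  lat <- c(0.229, 0.287, 0.367, 0.461)
  sgn <- c(1, -1, 1, -1)
  for (j in seq_along(lat)) {
    idx <- sample_range(lat[j] - 0.02, lat[j] + 0.02, fs)
    pk <- idx[which.max(abs(w[idx]))]
    expect_lt(abs((pk - 1) / fs - lat[j]), 0.006)
    expect_equal(sign(w[pk]), sgn[j])
  }
  # topography maximal at FCz/Cz
  tp <- execution_template()$topography
  labs <- default_montage()[1:28]
  expect_true(all(which(tp >= max(tp) - 1e-9) %in% match(c("FCz", "Cz"), labs)))
})

test_that("identical seeds give bit-identical sessions", {
  a <- generate_recording(simulation_config(duration_s = 30, seed = 9))
  b <- generate_recording(simulation_config(duration_s = 30, seed = 9))
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
})

test_that("execution-event spacing follows the end-to-onset renewal process", {
  cfg <- simulation_config(duration_s = 3600, seed = 3)
  for (s in 1:5) {
    on <- errpdetect:::with_seed(s, errpdetect:::draw_exec_onsets(cfg))
    expected <- 3600 / (mean(c(5, 8)) + 2)
    expect_gt(length(on), 0.9 * expected)
    expect_lt(length(on), 1.1 * expected)
    # never closer than the lower gap bound
    expect_true(all(diff(on) >= 5))
  }
})

test_that("snr_scale 0 leaves the event-locked average at background level", {
  sess <- cached_session(900, snr_scale = 0, seed = 401)
  rec <- sess$preprocessed
  ex <- extract_epochs(rec, sess$events, c(0, 1), "execution")
  fcz <- match("FCz", rec$channel_labels)
  avg <- colMeans(ex$epochs[, fcz, ])
  sem <- apply(ex$epochs[, fcz, ], 2, sd) / sqrt(length(ex$labels))
  z <- avg / sem
  # per-sample z-scores behave like a null: nothing extreme, ~99.7% within 3
  expect_lt(max(abs(z)), 5)
  expect_gt(mean(abs(z) < 3), 0.95)
})

test_that("averaging many event-locked epochs recovers the injected template", {
  sess <- cached_session(1800, snr_scale = 1, seed = 101)
  rec <- sess$preprocessed
  ex <- extract_epochs(rec, sess$events, c(0, 1), "execution")
  expect_gte(length(ex$labels), 200)
  fcz <- match("FCz", rec$channel_labels)
  avg <- colMeans(ex$epochs[, fcz, ])
  tpl <- sess$ground_truth$templates$execution[fcz, ]
  expect_gt(cor(avg, tpl), 0.9)
})

test_that("error-window low-frequency band power rises with injection strength", {
  bp <- sapply(c(0.5, 1, 2), function(snr) {
    sess <- cached_session(240, snr_scale = snr, seed = 55)
    rec <- sess$preprocessed
    cz <- match("Cz", rec$channel_labels)
    ex <- extract_epochs(rec, sess$events, c(0, 1), "execution")
    ts <- build_trialset(rec, sess$events)
    ne <- which(ts$labels == "noError")
    pw <- function(ep) {
      p <- welch_psd(t(ep[, cz, ]), rec$fs_Hz)
      mean(colSums(p$power[p$freq_Hz >= 1 & p$freq_Hz <= 7, , drop = FALSE]))
    }
    pw(ex$epochs) - pw(ts$epochs[ne, , , drop = FALSE])
  })
  expect_true(all(diff(bp) > 0))
})

test_that("generated event tables respect spacing and composition invariants", {
  sess <- cached_session(240, snr_scale = 1, seed = 55)
  ev <- as.data.frame(sess$events)
  expect_true(all(diff(ev$onset_s[ev$event_type == "execution"]) >= 5))
  expect_true(all(ev$event_type %in% c("execution", "outcome")))
  expect_true(all(is.na(ev$severity_deg[ev$event_type == "outcome"])))
  expect_true(all(ev$severity_deg[ev$event_type == "execution"] %in%
                    c(45, 90, 180, 270, 315)))
  expect_false(is.unsorted(ev$onset_s))
  # outcome errors never fall inside an execution perturbation
  exec <- ev[ev$event_type == "execution", ]
  for (t in ev$onset_s[ev$event_type == "outcome"])
    expect_false(any(t >= exec$onset_s & t <= exec$onset_s + exec$duration_s))
})
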