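# Synthetic continuous-feedback EEG session generator.
#
# Emulates the statistical structure the downstream analysis assumes: 1/f-like
# multichannel background, blink/saccade EOG artifacts leaking into frontal
# EEG, a 2-D thumbstick trace, and two families of injected error responses —
# execution errors (2-s feedback perturbations, severity in degrees, spaced
# 5-8 s end-to-onset) and sparse outcome errors (cursor-block collisions,
# Poisson at ~86/h). Each error adds a stereotyped event-related waveform
# (signed Gaussian bumps) plus a band-limited delta/theta power burst, both
# scaled by a frontocentral topography peaking at FCz/Cz.

#' Standard 28-channel scalp montage plus EOG and thumbstick labels
#' @return Character vector of 33 channel labels.
#' @export
default_montage <- function() {
  c("Fpz", "AFz", "F3", "Fz", "F4", "F8", "FC3", "FCz", "FC4", "T7", "C3",
    "Cz", "C4", "T8", "CP3", "CPz", "CP4", "P7", "P3", "Pz", "P4", "P8",
    "PO7", "POz", "PO8", "O1", "Oz", "O2",
    "EOG1", "EOG2", "EOG3", "stickX", "stickY")
}

montage_kinds <- function(labels = default_montage()) {
  ifelse(grepl("^EOG", labels), "eog",
         ifelse(grepl("^stick", labels), "stick", "eeg"))
}

# Frontocentral topography: gain in [0,1] per EEG channel, maximal at FCz/Cz.
default_topography <- function(eeg_labels) {
  gains <- c(Fpz = 0.25, AFz = 0.45, F3 = 0.45, Fz = 0.7, F4 = 0.45,
             F8 = 0.2, FC3 = 0.65, FCz = 1.0, FC4 = 0.65, T7 = 0.15,
             C3 = 0.6, Cz = 0.95, C4 = 0.6, T8 = 0.15, CP3 = 0.5,
             CPz = 0.7, CP4 = 0.5, P7 = 0.1, P3 = 0.35, Pz = 0.45,
             P4 = 0.35, P8 = 0.1, PO7 = 0.08, POz = 0.25, PO8 = 0.08,
             O1 = 0.05, Oz = 0.1, O2 = 0.05)
  out <- gains[eeg_labels]
  out[is.na(out)] <- 0.2
  unname(out)
}

#' Build an error-response template
#'
#' A template is a sum of signed Gaussian bumps (the time-locked potential)
#' plus a specification of band-limited power bursts (the spectral response),
#' both projected onto the scalp through a per-channel gain vector.
#'
#' @param kind `"execution"` or `"outcome"`.
#' @param components Data frame with columns `latency_s`, `amplitude_uV`,
#'   `width_s`, `sign` (+1/-1); latencies in `[0, 1)` s, widths positive.
#' @param topography Per-EEG-channel gain in `[0, 1]`; defaults to a
#'   frontocentral distribution maximal at FCz/Cz.
#' @param band_modulation Data frame with columns `band_lo_Hz`, `band_hi_Hz`,
#'   `duration_s`, `power_gain` describing additive noise bursts.
#' @param eeg_labels EEG channel labels the topography refers to.
#' @return An `errp_template` object.
#' @export
make_errp_template <- function(kind, components, topography = NULL,
                               band_modulation = NULL,
                               eeg_labels = default_montage()[1:28]) {
  if (!kind %in% c("execution", "outcome"))
    stop("unknown template kind: ", kind)
  components <- as.data.frame(components)
  stopifnot(all(c("latency_s", "amplitude_uV", "width_s", "sign") %in%
                  names(components)))
  if (nrow(components)) {
    if (any(components$latency_s < 0 | components$latency_s >= 1))
      stop("component latencies must lie in [0, 1) s")
    if (any(components$width_s <= 0))
      stop("component widths must be positive")
  }
  if (is.null(topography)) topography <- default_topography(eeg_labels)
  stopifnot(length(topography) == length(eeg_labels),
            all(topography >= 0), all(topography <= 1))
  if (is.null(band_modulation))
    band_modulation <- data.frame(band_lo_Hz = numeric(0),
                                  band_hi_Hz = numeric(0),
                                  duration_s = numeric(0),
                                  power_gain = numeric(0))
  structure(list(kind = kind, components = components,
                 topography = topography, band_modulation =
                   as.data.frame(band_modulation),
                 eeg_labels = eeg_labels),
            class = "errp_template")
}

#' Default execution-error template
#'
#' Four-component waveform: positive peak at 229 ms, negative at 287 ms,
#' positive at 367 ms, small negative at 461 ms, with a combined delta/theta
#' (1-7 Hz) power burst. Amplitudes are in microvolts at the topography
#' maximum (FCz).
#' @param eeg_labels EEG channel labels.
#' @export
execution_template <- function(eeg_labels = default_montage()[1:28]) {
  make_errp_template(
    "execution",
    data.frame(latency_s = c(0.229, 0.287, 0.367, 0.461),
               amplitude_uV = c(5.5, 6.5, 6.0, 2.8),
               width_s = c(0.022, 0.020, 0.030, 0.030),
               sign = c(1, -1, 1, -1)),
    band_modulation = data.frame(band_lo_Hz = c(1, 5), band_hi_Hz = c(4, 7),
                                 duration_s = c(1.0, 0.9),
                                 power_gain = c(3.5, 2.8)),
    eeg_labels = eeg_labels)
}

#' Default outcome-error template
#'
#' Negative peak at 2 ms (the collision is anticipated), positive at 268 ms,
#' negative at 486 ms, small positivity at 742 ms; broader and stronger than
#' the execution response, with delta/theta bursts.
#' @param eeg_labels EEG channel labels.
#' @export
outcome_template <- function(eeg_labels = default_montage()[1:28]) {
  make_errp_template(
    "outcome",
    data.frame(latency_s = c(0.002, 0.268, 0.486, 0.742),
               amplitude_uV = c(7.0, 9.0, 8.0, 3.5),
               width_s = c(0.060, 0.045, 0.060, 0.050),
               sign = c(-1, 1, -1, 1)),
    band_modulation = data.frame(band_lo_Hz = c(1, 5), band_hi_Hz = c(4, 7),
                                 duration_s = c(1.0, 0.85),
                                 power_gain = c(4.5, 3.6)),
    eeg_labels = eeg_labels)
}

#' Evaluate a template's deterministic waveform on a time grid
#'
#' @param template An `errp_template`.
#' @param fs_Hz Sampling rate.
#' @param duration_s Grid length (default 1 s).
#' @return Matrix, EEG channels x samples: the signed Gaussian-bump sum
#'   scaled by the topography. The stochastic band-limited burst is added at
#'   injection time, not here.
#' @export
evaluate_template <- function(template, fs_Hz, duration_s = 1) {
  n <- as.integer(round(duration_s * fs_Hz))
  t <- (seq_len(n) - 1) / fs_Hz
  wave <- rep(0, n)
  comp <- template$components
  for (j in seq_len(nrow(comp)))
    wave <- wave + comp$sign[j] * comp$amplitude_uV[j] *
      exp(-(t - comp$latency_s[j])^2 / (2 * comp$width_s[j]^2))
  outer(template$topography, wave)
}

# Band-limited noise burst with a Hann envelope; sd scaled to power_gain uV.
band_burst <- function(lo, hi, duration_s, power_gain, fs) {
  n <- as.integer(round(duration_s * fs))
  x <- stats::rnorm(n + 2 * fs)  # pad so the filter transient settles
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, x)[fs + seq_len(n)]
  x <- x / stats::sd(x) * power_gain
  x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Simulation configuration
#'
#' Defaults reproduce the recording conditions the pipeline is designed for:
#' 512 Hz, 28 EEG + 3 EOG channels plus a 2-D thumbstick trace, 2-s execution
#' perturbations spaced 5-8 s apart (measured end-to-onset) with severities
#' drawn from \{45, 90, 180, 270, 315\} degrees, and outcome errors as a
#' Poisson process at 86 per hour with a 1.5-s refractory period, thinned so
#' they never fall inside an execution perturbation.
#'
#' @param duration_s Session length in seconds.
#' @param fs_Hz Sampling rate (default 512).
#' @param exec_gap_s Bounds of the uniform end-to-onset gap between execution
#'   errors.
#' @param exec_duration_s Perturbation length (default 2 s).
#' @param severities Severity values in degrees.
#' @param severity_weights Sampling weights over `severities`.
#' @param outcome_rate_per_h Outcome-error rate (default 86).
#' @param snr_scale Global multiplier on injected template amplitudes and
#'   band bursts; 0 disables injection.
#' @param severity_scales Optional per-severity amplitude multipliers (same
#'   length as `severities`). Default `NULL`: severity changes only the event
#'   label, not the waveform.
#' @param background_sd_uV Standard deviation of the EEG background.
#' @param ar_coefs AR coefficients of the per-channel background process.
#' @param spatial_rho Share of a common process mixed into every EEG channel.
#' @param blink_rate_per_min,saccade_rate_per_min,blink_amplitude_uV EOG
#'   artifact parameters.
#' @param eog_leakage Peak EOG-to-EEG leakage gain at frontal channels.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(duration_s = 3600, fs_Hz = 512,
                              exec_gap_s = c(5, 8), exec_duration_s = 2,
                              severities = c(45, 90, 180, 270, 315),
                              severity_weights = rep(1, 5),
                              outcome_rate_per_h = 86,
                              snr_scale = 1, severity_scales = NULL,
                              background_sd_uV = 10,
                              ar_coefs = c(0.5, 0.15, 0.05, 0.02),
                              spatial_rho = 0.5,
                              blink_rate_per_min = 15,
                              saccade_rate_per_min = 20,
                              blink_amplitude_uV = 100,
                              eog_leakage = 0.25,
                              seed = 1L) {
  stopifnot(exec_gap_s[1] <= exec_gap_s[2], outcome_rate_per_h >= 0,
            snr_scale >= 0, fs_Hz > 2 * 60,
            length(severity_weights) == length(severities))
  if (!is.null(severity_scales))
    stopifnot(length(severity_scales) == length(severities))
  structure(as.list(environment()), class = "sim_config")
}

# Draw execution-error onsets: gap ~ U(gap), measured end of the 2-s
# perturbation to the next onset. First onset after an initial gap.
draw_exec_onsets <- function(cfg) {
  onsets <- numeric(0)
  t <- stats::runif(1, cfg$exec_gap_s[1], cfg$exec_gap_s[2])
  # stop early enough that the perturbation and a 1-s epoch both fit
  while (t + cfg$exec_duration_s + 1 <= cfg$duration_s) {
    onsets <- c(onsets, t)
    t <- t + cfg$exec_duration_s +
      stats::runif(1, cfg$exec_gap_s[1], cfg$exec_gap_s[2])
  }
  onsets
}

# Poisson outcome onsets with refractory period, thinned against execution
# perturbation intervals.
draw_outcome_onsets <- function(cfg, exec_onsets) {
  rate <- cfg$outcome_rate_per_h / 3600
  n_cand <- stats::rpois(1, rate * cfg$duration_s * 1.5)
  cand <- sort(stats::runif(n_cand, 1, max(cfg$duration_s - 1.5, 1)))
  kept <- numeric(0)
  last <- -Inf
  for (t in cand) {
    if (t - last < 1.5) next
    inside <- any(t >= exec_onsets - 0.5 &
                    t <= exec_onsets + cfg$exec_duration_s + 0.5)
    if (inside) next
    kept <- c(kept, t); last <- t
  }
  target <- rate * cfg$duration_s
  if (length(kept) > target) kept <- sort(sample(kept, round(target)))
  kept
}

#' Generate a synthetic continuous recording with ground truth
#'
#' Produces the full session: autoregressive spatially correlated EEG
#' background, EOG blink/saccade channels with frontal leakage into the EEG,
#' a smoothed-random-walk thumbstick trace with corrective deflections during
#' perturbations, and injected execution/outcome error responses at the drawn
#' event times. The same seed yields a bit-identical session.
#'
#' @param config A `sim_config`.
#' @return List with `recording` (an `errp_recording`), `events` (an
#'   `errp_events` table) and `ground_truth` (templates as evaluated
#'   channel-by-sample matrices plus the event table).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    fs <- cfg$fs_Hz
    n <- as.integer(round(cfg$duration_s * fs))
    labels <- default_montage()
    kinds <- montage_kinds(labels)
    n_eeg <- sum(kinds == "eeg")

    # --- events ------------------------------------------------------------
    exec_on <- draw_exec_onsets(cfg)
    if (length(exec_on) == 0)
      warning("duration too short to host a single execution event")
    sev <- if (length(exec_on))
      sample(cfg$severities, length(exec_on), replace = TRUE,
             prob = cfg$severity_weights) else numeric(0)
    out_on <- draw_outcome_onsets(cfg, exec_on)
    ord <- order(c(exec_on, out_on))
    events <- event_table(
      onset_s = c(exec_on, out_on)[ord],
      duration_s = c(rep(cfg$exec_duration_s, length(exec_on)),
                     rep(0, length(out_on)))[ord],
      event_type = c(rep("execution", length(exec_on)),
                     rep("outcome", length(out_on)))[ord],
      severity_deg = c(sev, rep(NA_real_, length(out_on)))[ord],
      recording_duration_s = cfg$duration_s)

    # --- background EEG -----------------------------------------------------
    sig <- matrix(0, length(labels), n)
    shared <- stats::filter(stats::rnorm(n), cfg$ar_coefs,
                            method = "recursive")
    shared <- shared / stats::sd(shared)
    rho <- cfg$spatial_rho
    for (c in which(kinds == "eeg")) {
      x <- stats::filter(stats::rnorm(n), cfg$ar_coefs, method = "recursive")
      x <- x / stats::sd(x)
      sig[c, ] <- cfg$background_sd_uV * (sqrt(1 - rho^2) * x + rho * shared)
    }

    # --- EOG artifacts ------------------------------------------------------
    eog_idx <- which(kinds == "eog")
    eog_clean <- matrix(0, length(eog_idx), n)
    n_blink <- stats::rpois(1, cfg$blink_rate_per_min * cfg$duration_s / 60)
    blink_t <- stats::runif(n_blink, 0.3, cfg$duration_s - 0.3)
    blink_gain <- c(1, 1, 0.8)
    tgrid <- (seq_len(as.integer(0.4 * fs)) - 1) / fs - 0.2
    blink_shape <- exp(-tgrid^2 / (2 * 0.05^2))
    for (bt in blink_t) {
      i0 <- as.integer(round((bt - 0.2) * fs))
      idx <- i0 + seq_along(blink_shape)
      idx_ok <- idx >= 1 & idx <= n
      amp <- cfg$blink_amplitude_uV * stats::runif(1, 0.7, 1.3)
      for (k in seq_along(eog_idx))
        eog_clean[k, idx[idx_ok]] <- eog_clean[k, idx[idx_ok]] +
          amp * blink_gain[k] * blink_shape[idx_ok]
    }
    n_sacc <- stats::rpois(1, cfg$saccade_rate_per_min * cfg$duration_s / 60)
    sacc_t <- sort(stats::runif(n_sacc, 0, cfg$duration_s))
    sacc_sig <- rep(0, n)
    level <- 0
    prev <- 1L
    for (st in sacc_t) {
      i <- max(1L, as.integer(round(st * fs)))
      sacc_sig[prev:i] <- level
      level <- level + stats::rnorm(1, 0, 20)
      level <- max(min(level, 60), -60)
      prev <- i
    }
    sacc_sig[prev:n] <- level
    sacc_sig <- stats::filter(sacc_sig, rep(1 / 16, 16), sides = 1)
    sacc_sig[is.na(sacc_sig)] <- 0
    sacc_gain <- c(0.7, -0.7, 0.2)
    for (k in seq_along(eog_idx))
      eog_clean[k, ] <- eog_clean[k, ] + sacc_gain[k] * sacc_sig
    # recorded EOG = artifact + its own small background
    for (k in seq_along(eog_idx)) {
      bg <- stats::filter(stats::rnorm(n), cfg$ar_coefs, method = "recursive")
      sig[eog_idx[k], ] <- eog_clean[k, ] + 5 * bg / stats::sd(bg)
    }
    # leakage into EEG, strongest frontally
    frontal <- c(Fpz = 1, AFz = 0.85, F3 = 0.6, Fz = 0.6, F4 = 0.6, F8 = 0.5,
                 FC3 = 0.35, FCz = 0.35, FC4 = 0.35)
    leak_gain <- frontal[labels[kinds == "eeg"]]
    leak_gain[is.na(leak_gain)] <- 0.08
    leak <- outer(unname(leak_gain) * cfg$eog_leakage, c(0.5, 0.5, 0.3))
    sig[kinds == "eeg", ] <- sig[kinds == "eeg", ] + leak %*% eog_clean

    # --- thumbstick ---------------------------------------------------------
    stick_idx <- which(kinds == "stick")
    walk <- matrix(0, 2, n)
    for (k in 1:2) {
      w <- cumsum(stats::rnorm(n, 0, 0.004))
      w <- stats::filter(w, rep(1 / 64, 64), sides = 1)
      w[is.na(w)] <- 0
      walk[k, ] <- w
    }
    # corrective deflection during perturbations (weakly informative confound)
    for (j in seq_along(exec_on)) {
      idx <- sample_range(exec_on[j] + 0.3, exec_on[j] + cfg$exec_duration_s, fs)
      idx <- idx[idx <= n]
      ramp <- seq(0, 1, length.out = length(idx))
      ang <- sev[j] * pi / 180
      walk[1, idx] <- walk[1, idx] + 0.08 * cos(ang) * ramp
      walk[2, idx] <- walk[2, idx] + 0.08 * sin(ang) * ramp
    }
    sig[stick_idx, ] <- tanh(walk)     # keep in [-1, 1]

    # --- inject error responses --------------------------------------------
    exec_tpl <- execution_template(labels[kinds == "eeg"])
    out_tpl <- outcome_template(labels[kinds == "eeg"])
    tpl_mat <- list(execution = evaluate_template(exec_tpl, fs),
                    outcome = evaluate_template(out_tpl, fs))
    tpl_obj <- list(execution = exec_tpl, outcome = out_tpl)
    eeg_rows <- which(kinds == "eeg")
    if (cfg$snr_scale > 0) {
      for (j in seq_len(nrow(events))) {
        tp <- events$event_type[j]
        scale <- cfg$snr_scale
        if (tp == "execution" && !is.null(cfg$severity_scales))
          scale <- scale *
            cfg$severity_scales[match(events$severity_deg[j], cfg$severities)]
        i0 <- as.integer(round(events$onset_s[j] * fs))
        tpl <- tpl_mat[[tp]]
        idx <- i0 + seq_len(ncol(tpl))
        ok <- idx <= n
        sig[eeg_rows, idx[ok]] <- sig[eeg_rows, idx[ok]] +
          scale * tpl[, ok, drop = FALSE]
        bm <- tpl_obj[[tp]]$band_modulation
        for (b in seq_len(nrow(bm))) {
          burst <- band_burst(bm$band_lo_Hz[b], bm$band_hi_Hz[b],
                              bm$duration_s[b], bm$power_gain[b] * scale, fs)
          bidx <- i0 + seq_along(burst)
          bok <- bidx <= n
          sig[eeg_rows, bidx[bok]] <- sig[eeg_rows, bidx[bok]] +
            outer(tpl_obj[[tp]]$topography, burst[bok])
        }
      }
    }

    rec <- recording(sig, fs, labels, kinds,
                     metadata = list(seed = cfg$seed, generator = "synthgen",
                                     snr_scale = cfg$snr_scale,
                                     pipeline = character(0)))
    list(recording = rec, events = events,
         ground_truth = list(events = events, templates = tpl_mat,
                             template_objects = tpl_obj))
  })
}
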