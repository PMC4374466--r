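# Containers and I/O for continuous recordings and event tables.

#' Construct a continuous multichannel recording
#'
#' The basic container moved through the pipeline: a channels-by-samples
#' signal matrix in microvolts plus channel metadata. Channel kinds separate
#' scalp EEG from EOG and from the thumbstick trace, which downstream stages
#' treat differently (e.g. common-average referencing uses EEG channels only).
#'
#' @param signal Numeric matrix, channels x samples, microvolts.
#' @param fs_Hz Sampling rate in Hz.
#' @param channel_labels Character vector, one unique label per channel.
#' @param channel_kinds Character vector in `c("eeg", "eog", "stick")`.
#' @param metadata Optional named list (seed, provenance flags, ...).
#' @return An object of class `errp_recording`.
#' @export
recording <- function(signal, fs_Hz, channel_labels, channel_kinds,
                      metadata = list()) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(signal), fs_Hz > 0)
  if (length(channel_labels) != nrow(signal))
    stop("channel_labels length must match the number of signal rows")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (length(channel_kinds) != nrow(signal) ||
      !all(channel_kinds %in% c("eeg", "eog", "stick")))
    stop("channel_kinds must be one of 'eeg', 'eog', 'stick' per channel")
  if (!all(is.finite(signal)))
    stop("signal must be finite")
  rownames(signal) <- channel_labels
  structure(list(signal = signal, fs_Hz = fs_Hz,
                 channel_labels = as.character(channel_labels),
                 channel_kinds = as.character(channel_kinds),
                 metadata = metadata),
            class = "errp_recording")
}

#' @export
print.errp_recording <- function(x, ...) {
  cat(sprintf("<errp_recording> %d channels (%d EEG, %d EOG, %d stick), %.1f s @ %g Hz\n",
              nrow(x$signal), sum(x$channel_kinds == "eeg"),
              sum(x$channel_kinds == "eog"), sum(x$channel_kinds == "stick"),
              ncol(x$signal) / x$fs_Hz, x$fs_Hz))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `errp_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs_Hz

#' Construct and validate an event table
#'
#' @param onset_s Event onsets in seconds (sorted ascending).
#' @param duration_s Event durations in seconds (0 for point events).
#' @param event_type `"execution"` or `"outcome"` per event.
#' @param severity_deg Perturbation severity in degrees for execution errors,
#'   `NA` for outcome errors.
#' @param recording_duration_s Optional; onsets beyond it are rejected.
#' @return A `data.frame` of class `errp_events` with the four columns.
#' @export
event_table <- function(onset_s = numeric(0), duration_s = numeric(0),
                        event_type = character(0), severity_deg = NA_real_,
                        recording_duration_s = NULL) {
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   event_type = as.character(event_type),
                   severity_deg = as.numeric(rep_len(severity_deg,
                                                     length(onset_s))))
  if (nrow(ev)) {
    if (is.unsorted(ev$onset_s)) stop("event onsets must be sorted ascending")
    if (!all(ev$event_type %in% c("execution", "outcome")))
      stop("event_type must be 'execution' or 'outcome'")
    if (any(ev$onset_s < 0)) stop("event onsets must be non-negative")
    if (!is.null(recording_duration_s) &&
        any(ev$onset_s > recording_duration_s))
      stop("event onset beyond recording duration")
  }
  class(ev) <- c("errp_events", "data.frame")
  ev
}

#' Read / write an event table as tab-separated text
#'
#' Columns: `onset_s`, `duration_s`, `event_type`, `severity_deg` (empty for
#' outcome errors). A sidecar TSV is used rather than EDF annotations because
#' annotations cannot carry the severity metadata losslessly.
#'
#' @param path File path.
#' @param events An `errp_events` table (write).
#' @param recording_duration_s Optional validation bound (read).
#' @return `read_events` returns an `errp_events` table.
#' @export
read_events <- function(path, recording_duration_s = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(event_table())
  event_table(df$onset_s, df$duration_s, df$event_type,
              df$severity_deg %||% NA_real_, recording_duration_s)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# EDF I/O. Minimal single-session EDF (16-bit) codec: fixed-length header,
# one-second data records, little-endian int16 samples scaled between the
# per-channel physical and digital ranges. Sufficient for round-tripping the
# sessions this pipeline produces; not a general-purpose EDF+ implementation.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file (with sidecar event TSV)
#'
#' Signals are quantized to 16 bits between each channel's physical min/max,
#' the standard EDF encoding; the round-trip error is bounded by half a
#' quantization step. The recording is zero-padded to a whole number of
#' one-second data records.
#'
#' @param rec An `errp_recording`.
#' @param path Output `.edf` path. If `events` is supplied, a sibling file
#'   `<path without .edf>_events.tsv` is written.
#' @param events Optional `errp_events` table.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, events = NULL) {
  stopifnot(inherits(rec, "errp_recording"))
  fs <- rec$fs_Hz
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$signal)
  n_rec <- as.integer(ceiling(ncol(rec$signal) / fs))
  sig <- rec$signal
  if (ncol(sig) < n_rec * fs)
    sig <- cbind(sig, matrix(0, ns, n_rec * fs - ncol(sig)))

  pmin <- apply(sig, 1, min); pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(edf_pad(x, width), collapse = ""),
                                     con, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(n_rec, 8); wr(1, 8); wr(ns, 4)
  for (i in seq_len(ns)) wr(rec$channel_labels[i], 16)
  for (i in seq_len(ns)) wr(rec$channel_kinds[i], 80)
  for (i in seq_len(ns)) wr(if (rec$channel_kinds[i] == "stick") "au" else "uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", pmin[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", pmax[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    dig <- round((sig[, idx, drop = FALSE] - pmin) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  if (!is.null(events))
    write_events(events, sub("\\.edf$", "_events.tsv", path))
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' @param path `.edf` path; if a sibling `<stem>_events.tsv` exists, events
#'   are read and validated against the recording duration.
#' @return A list with elements `recording` and `events` (`NULL` when no
#'   sidecar file exists).
#' @export
read_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  kinds <- vapply(seq_len(ns), function(i) rd(80), "")
  for (i in seq_len(ns)) rd(8)            # dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / rec_dur

  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    dig <- matrix(raw, nrow = spr[1], ncol = ns)
    phys <- t((t(dig) - dmin) * (pmax - pmin) / (dmax - dmin) + pmin)
    sig[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(phys)
  }
  if (!kinds[1] %in% c("eeg", "eog", "stick"))
    kinds <- rep("eeg", ns)  # foreign EDF: transducer field not ours
  rec <- recording(sig, fs, labels, kinds)
  ev_path <- sub("\\.edf$", "_events.tsv", path)
  events <- if (file.exists(ev_path))
    read_events(ev_path, recording_duration_s = recording_duration(rec))
  else NULL
  list(recording = rec, events = events)
}

# ---------------------------------------------------------------------------

#' Cut a continuous recording into fixed-length event-locked epochs
#'
#' Epoch sample 0 is aligned to the event onset plus `window[1]`; windows are
#' half-open `[start, end)` at the recording's sampling rate, so a 1-s window
#' at 512 Hz yields exactly 512 samples. Events whose window does not fit
#' inside the recording are dropped (with a message).
#'
#' @param rec An `errp_recording`.
#' @param events An `errp_events` table.
#' @param window Length-2 numeric, `c(start_s, end_s)` relative to onset.
#' @param event_filter Optional predicate over event rows, or a character
#'   vector of event types to keep.
#' @return A `trialset`: list with `epochs` (trials x channels x samples
#'   array), `labels` (event types), `severity` (degrees), `window`, `fs_Hz`,
#'   `onsets` (kept onsets).
#' @export
extract_epochs <- function(rec, events, window = c(0, 1),
                           event_filter = NULL) {
  stopifnot(inherits(rec, "errp_recording"), length(window) == 2,
            window[1] < window[2])
  ev <- as.data.frame(events)
  if (!is.null(event_filter)) {
    keep <- if (is.character(event_filter)) ev$event_type %in% event_filter
            else vapply(seq_len(nrow(ev)),
                        function(i) isTRUE(event_filter(ev[i, ])), TRUE)
    ev <- ev[keep, , drop = FALSE]
  }
  fs <- rec$fs_Hz
  rel <- sample_range(window[1], window[2], fs)   # indices for onset at t=0
  n_samp <- length(rel)
  n_total <- ncol(rec$signal)
  onset_idx <- as.integer(round(ev$onset_s * fs)) # 0-based onset sample
  first <- onset_idx + rel[1]                     # 1-based first epoch sample
  fits <- first >= 1 & (first + n_samp - 1L) <= n_total
  if (any(!fits))
    message(sprintf("extract_epochs: dropped %d event(s) whose window does not fit",
                    sum(!fits)))
  ev <- ev[fits, , drop = FALSE]; first <- first[fits]
  n_tr <- nrow(ev)
  epochs <- array(0, dim = c(n_tr, nrow(rec$signal), n_samp))
  for (t in seq_len(n_tr))
    epochs[t, , ] <- rec$signal[, first[t] + 0:(n_samp - 1L)]
  structure(list(epochs = epochs, labels = ev$event_type,
                 severity = ev$severity_deg, window = window, fs_Hz = fs,
                 onsets = ev$onset_s,
                 channel_labels = rec$channel_labels,
                 channel_kinds = rec$channel_kinds),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<trialset> %d trials x %d channels x %d samples, window [%g, %g) s @ %g Hz\n",
              d[1], d[2], d[3], x$window[1], x$window[2], x$fs_Hz))
  if (d[1]) print(table(x$labels))
  invisible(x)
}

# Concatenate trialsets sharing geometry (used by fold assembly).
bind_trialsets <- function(a, b) {
  stopifnot(identical(dim(a$epochs)[2:3], dim(b$epochs)[2:3]),
            a$fs_Hz == b$fs_Hz)
  epochs <- array(0, dim = c(dim(a$epochs)[1] + dim(b$epochs)[1],
                             dim(a$epochs)[2], dim(a$epochs)[3]))
  if (dim(a$epochs)[1]) epochs[seq_len(dim(a$epochs)[1]), , ] <- a$epochs
  if (dim(b$epochs)[1])
    epochs[dim(a$epochs)[1] + seq_len(dim(b$epochs)[1]), , ] <- b$epochs
  structure(list(epochs = epochs, labels = c(a$labels, b$labels),
                 severity = c(a$severity, b$severity), window = a$window,
                 fs_Hz = a$fs_Hz, onsets = c(a$onsets, b$onsets),
                 channel_labels = a$channel_labels,
                 channel_kinds = a$channel_kinds),
            class = "trialset")
}

# Row-subset a trialset.
subset_trialset <- function(ts, idx) {
  structure(list(epochs = ts$epochs[idx, , , drop = FALSE],
                 labels = ts$labels[idx], severity = ts$severity[idx],
                 window = ts$window, fs_Hz = ts$fs_Hz,
                 onsets = ts$onsets[idx],
                 channel_labels = ts$channel_labels,
                 channel_kinds = ts$channel_kinds),
            class = "trialset")
}
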