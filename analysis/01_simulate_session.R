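#!/usr/bin/env Rscript
# Stage 1: simulate a continuous-feedback EEG session.
#
# Generates a 20-minute synthetic session at the default (realistic) SNR:
# 28 EEG + 3 EOG channels + thumbstick at 512 Hz, 2-s execution-error
# perturbations spaced 5-8 s apart with severities in {45, 90, 180, 270,
# 315} degrees, and sparse outcome errors (~86/h). Writes the raw session
# as EDF with a sidecar event TSV under results/session/.

library(errpdetect)

seed <- 20L
dur <- 1200
dir.create("results/session", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(duration_s = dur, snr_scale = 1, seed = seed)
sess <- generate_recording(cfg)

cat(sprintf("Simulated %.0f-min session (seed %d):\n", dur / 60, seed))
print(table(sess$events$event_type))
ex <- sess$events[sess$events$event_type == "execution", ]
cat("severity counts:\n")
print(table(ex$severity_deg))
cat(sprintf("median end-to-onset gap: %.2f s (configured 5-8 s)\n",
            median(diff(ex$onset_s)) - cfg$exec_duration_s))

write_recording(sess$recording, "results/session/session.edf",
                events = sess$events)
cat("wrote results/session/session.edf and session_events.tsv\n")
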