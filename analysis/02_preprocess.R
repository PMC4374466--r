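#!/usr/bin/env Rscript
# Stage 2: signal conditioning.
#
# Reads the raw session, applies the canonical chain -- 0.5-60 Hz band-pass
# with 50 Hz notch (zero-phase), EOG artifact regression, common-average
# reference -- and writes the cleaned recording. Reports how strongly the
# EOG leaked into frontal channels before and after correction.

library(errpdetect)

io <- read_recording("results/session/session.edf")
rec <- io$recording

filt <- filter_signal(rec)
model <- fit_eog_regression(filt)
clean <- common_average(apply_eog_regression(filt, model))

eog1 <- filt$signal[filt$channel_labels == "EOG1", ]
for (ch in c("Fpz", "FCz", "POz")) {
  i <- match(ch, filt$channel_labels)
  cat(sprintf("%-4s |cor with EOG1| before: %.3f  after: %.3f\n", ch,
              abs(cor(filt$signal[i, ], eog1)),
              abs(cor(clean$signal[i, ], eog1))))
}
cat(sprintf("max per-sample EEG mean after CAR: %.2e uV\n",
            max(abs(colMeans(clean$signal[clean$channel_kinds == "eeg", ])))))

write_recording(clean, "results/session/session_clean.edf",
                events = io$events)
cat("wrote results/session/session_clean.edf\n")
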