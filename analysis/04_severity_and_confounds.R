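#!/usr/bin/env Rscript
# Stage 4: severity contrasts and confound controls.
#
# Tests whether the severity of an execution error (45-315 degrees) is
# decodable -- under the generator's default severity-independent injection
# it should not be -- and repeats the error-vs-noError classification on the
# EOG channels and on the thumbstick trace alone, to check that eye or hand
# movement could not explain the EEG results. Writes
# results/severity_confounds.tsv.

library(errpdetect)

seed <- 22L
io <- read_recording("results/session/session_clean.edf")
ts <- build_trialset(io$recording, io$events)

sev <- severity_contrasts(ts, mode = "freq", k = 5, seed = seed)
cat("severity contrasts (chance = 50%):\n")
print(transform(sev, accuracy_pct = round(100 * accuracy, 1))[
  c("contrast", "n_trials", "accuracy_pct")])

rows <- list()
for (chans in c("eog", "stick")) {
  for (cn in list(c("execution", "noError"), c("outcome", "noError"))) {
    keep <- ts$labels %in% cn
    fm <- balance_classes(build_feature_matrix(
      errpdetect:::subset_trialset(ts, keep), mode = "time",
      channels = chans), seed = seed)
    cv <- crossvalidate(fm, k = 5, seed = seed)
    rows[[length(rows) + 1]] <-
      data.frame(contrast = paste(cn, collapse = "_vs_"), channels = chans,
                 n_trials = length(fm$labels),
                 accuracy_pct = round(100 * cv$accuracy, 1))
    cat(sprintf("confound %-5s %-22s acc %.1f%%\n", chans,
                paste(cn, collapse = " vs "), 100 * cv$accuracy))
  }
}
out <- rbind(
  data.frame(contrast = sev$contrast, channels = "eeg",
             n_trials = sev$n_trials,
             accuracy_pct = round(100 * sev$accuracy, 1)),
  do.call(rbind, rows))
write.table(out, "results/severity_confounds.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/severity_confounds.tsv\n")
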