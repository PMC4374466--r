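#!/usr/bin/env Rscript
# Stage 6: waveform statistics and summary report.
#
# Computes the execution/outcome difference waveforms at FCz with
# Bonferroni-corrected pointwise significance intervals, summarizes the
# stage 3-5 tables, and compares the bundled ten-subject reference tables'
# group means with our synthetic-session results. Writes
# results/summary.json.

library(errpdetect)
library(jsonlite)

io <- read_recording("results/session/session_clean.edf")
ts <- build_trialset(io$recording, io$events)

summary <- list()
for (kind in c("execution", "outcome")) {
  a <- errpdetect:::subset_trialset(ts, ts$labels == kind)
  b <- errpdetect:::subset_trialset(ts, ts$labels == "noError")
  st <- erp_difference_stats(a, b, channel = "FCz")
  cat(sprintf("%s vs noError at FCz: %d significant interval(s)\n",
              kind, nrow(st$intervals)))
  if (nrow(st$intervals))
    print(transform(st$intervals,
                    peak_latency_ms = round(1000 * peak_latency_s),
                    peak_uV = round(peak_uV, 2))[
      c("start_s", "end_s", "peak_latency_ms", "peak_uV")])
  summary[[paste0(kind, "_significant_intervals")]] <- st$intervals
  summary[[paste0(kind, "_peak_latency_ms")]] <-
    1000 * st$time_s[which.max(abs(st$difference))]
}

for (f in c("event_locked", "severity_confounds", "async_performance")) {
  path <- sprintf("results/%s.tsv", f)
  if (file.exists(path)) summary[[f]] <- read.delim(path)
}
summary$reference_event_locked_means <-
  as.list(round(aggregate_report(reference_results("event_locked")), 1))
summary$reference_async_means <-
  as.list(round(aggregate_report(reference_results("async")), 3))

write_json(summary, "results/summary.json", auto_unbox = TRUE, digits = 4,
           dataframe = "rows")
cat("wrote results/summary.json\n")
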