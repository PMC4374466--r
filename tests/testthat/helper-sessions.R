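# Session cache shared across test files: generating and preprocessing a
# synthetic session is the expensive step, so each (duration, snr, seed)
# combination is built once per test run.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(duration_s, snr_scale = 1, seed = 101L,
                           preprocess = TRUE, ...) {
  key <- paste(duration_s, snr_scale, seed, preprocess,
               paste(deparse(substitute(list(...))), collapse = ""), sep = "|")
  if (!is.null(.session_cache[[key]])) return(.session_cache[[key]])
  cfg <- simulation_config(duration_s = duration_s, snr_scale = snr_scale,
                           seed = seed, ...)
  sess <- generate_recording(cfg)
  if (preprocess) {
    sess$preprocessed <- preprocess_recording(sess$recording)
    sess$recording <- NULL    # keep the cache footprint down
  }
  .session_cache[[key]] <- sess
  sess
}

# Rank-based (Mann-Whitney) AUC: the independent oracle for the
# threshold-sweep implementation. Counts strictly-greater pairs plus half
# the ties.
rank_auc <- function(p, labels) {
  pos <- p[as.logical(labels)]
  neg <- p[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
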