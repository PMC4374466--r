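# Shared time-indexing and RNG helpers.
#
# Time convention used throughout: seconds, 0-based sample indices, half-open
# windows [t0, t1). Sample i of a signal at sampling rate fs covers time i/fs,
# so the samples falling in [t0, t1) are i = ceiling(t0*fs) .. ceiling(t1*fs)-1.

#' Sample indices covering a half-open time window
#'
#' Returns the 1-based sample indices whose times `i/fs` (0-based `i`) fall in
#' the half-open interval `[t0, t1)`.
#'
#' @param t0,t1 Window edges in seconds, `t0 < t1`.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of 1-based indices.
#' @keywords internal
sample_range <- function(t0, t1, fs) {
  i0 <- as.integer(ceiling(t0 * fs - 1e-9))
  i1 <- as.integer(ceiling(t1 * fs - 1e-9)) - 1L
  if (i1 < i0) return(integer(0))
  seq.int(i0, i1) + 1L
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed; keeps values in 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12345L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
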