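# internal helpers

# evaluate code under a local seed without disturbing the caller's RNG;
# NULL seed means "use the current RNG stream"
with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# centred moving average whose window shrinks at the edges (no NA padding)
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  half <- n %/% 2L
  len <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(len) - half, 1L)
  hi <- pmin(seq_len(len) + half, len)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# window length in samples for a time window (always odd, >= 1)
samples_for <- function(window_s, dt) {
  k <- max(1L, round(window_s / dt))
  if (k %% 2L == 0L) k + 1L else k
}
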