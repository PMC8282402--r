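# Shared fixtures and independent oracles used across test files.

# Independent ARMA simulator (stats::arima.sim), used as the oracle-side
# generator so recovery tests do not reuse the package's own simulator.
sim_arma <- function(n, ar = numeric(0), ma = numeric(0), seed = 1, sd = 1) {
  withr::with_seed(seed, as.numeric(stats::arima.sim(
    model = list(ar = ar, ma = ma), n = n, sd = sd)))
}

# Reference EGARCH truth used in several recovery tests: sign coefficient
# -0.1, magnitude 0.2, persistence 0.9, unit unconditional variance.
egarch_truth <- function() {
  vol_params(0, alpha = 1, beta = 0.9, theta = -0.1, lambda = 0.2)
}

# Exhaustive signed-rank null: distribution of W over all 2^n sign patterns
# for a fixed vector of absolute differences (midranks for ties).
enumerate_signed_rank <- function(abs_d) {
  n <- length(abs_d)
  r <- rank(abs_d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  w
}

# Minimal WFDB format-16 writer for round-trip tests (single channel).
write_wfdb16_fixture <- function(dir, record, adc, fs = 100, gain = 200,
                                 baseline = 0) {
  hea <- file.path(dir, paste0(record, ".hea"))
  dat <- paste0(record, ".dat")
  writeLines(c(
    sprintf("%s 1 %g %d", record, fs, length(adc)),
    sprintf("%s 16 %g(%d)/mV 16 0 %d 0 0 ECG", dat, gain, baseline, adc[1])
  ), hea)
  writeBin(as.integer(adc), file.path(dir, dat), size = 2L, endian = "little")
  hea
}

# Minimal MIT annotation writer: one annotation per minute, codes 8 (apnea) /
# 1 (normal). Increments above the 10-bit field go through SKIP words with a
# 4-byte PDP-11 long offset (high word first), the same layout the reader
# expects.
write_apn_fixture <- function(path, codes, interval) {
  word_bytes <- function(w) as.raw(c(w %% 256L, w %/% 256L))
  out <- raw(0)
  for (i in seq_along(codes)) {
    inc <- if (i == 1) 0L else as.integer(interval)
    if (inc > 1023L) {
      out <- c(out, word_bytes(bitwShiftL(59L, 10)),
               word_bytes(inc %/% 65536L), word_bytes(inc %% 65536L))
      inc <- 0L
    }
    out <- c(out, word_bytes(bitwOr(bitwShiftL(codes[i], 10), inc)))
  }
  out <- c(out, word_bytes(0L)) # EOF
  writeBin(out, path)
  path
}
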