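# Independent brute-force oracles used to cross-check the implementation.

# Dominant frequency of a trace by direct DFT of the full record
# (rectangular window, no segmenting): argmax of |X|^2 inside `band`.
oracle_dft_peak <- function(x, fs, band) {
  n <- length(x)
  X <- fft(x - mean(x))
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  p <- Mod(X)^2
  freqs[keep][which.max(p[keep])]
}

# Exhaustive peak-detection oracle: scan every sample for a strict local
# maximum above the height threshold, then prune tallest-first so that no
# two kept peaks are closer than min_sep seconds. Nested loops on
# purpose - written independently of the vectorised implementation.
oracle_find_peaks <- function(x, fs, height, min_sep) {
  cand <- integer(0)
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1] && x[i] >= height)
      cand <- c(cand, i)
  }
  ord <- cand[order(-x[cand], cand)]
  min_sep_samples <- round(fs * min_sep) - 1
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (abs(i - j) < min_sep_samples) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort((kept - 1) / fs)
}

# Count narrow pulses in an ECG-like trace by thresholding at half the
# maximum and counting rising edges.
oracle_count_pulses <- function(x) {
  above <- x > max(x) / 2
  sum(diff(above) == 1) + as.integer(above[1])
}

# Small, fast simulation config for tests.
quick_config <- function(...) {
  sim_config(...)
}
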