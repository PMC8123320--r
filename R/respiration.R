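#' Detect inspiratory peaks in a respiratory trace
#'
#' Local maxima subject to a temporal and an amplitude constraint, the
#' breath-by-breath detection rule: minimum peak separation equal to the
#' period of the trial-average respiratory rate (`60 / avg_rr` seconds,
#' the inverse of the frequency-domain RR estimate; enforced on the
#' sampling grid with one sample of slack for quantization) and minimum
#' height
#' `amp_fraction` times the RMS of the trace over the analysis segment.
#' When two candidate peaks violate the separation, the taller is kept
#' (tallest-first greedy pruning). The fused wearable signal uses
#' `amp_fraction = 0.50`; the reference respiratory waveform uses `0.40`.
#'
#' @param x respiratory trace (band-pass conditioned, zero-mean; pass the
#'   analysis segment only, since its RMS sets the height threshold).
#' @param fs sampling rate, Hz.
#' @param avg_rr trial-average RR, breaths/min (> 0), normally the
#'   [rr_from_spectrum()] estimate.
#' @param amp_fraction height threshold as a fraction of the trace RMS,
#'   in (0, infinity); values above the trace maximum yield zero peaks.
#' @return Sorted peak times in seconds (relative to the start of `x`);
#'   may be empty.
#' @export
detect_breath_peaks <- function(x, fs, avg_rr, amp_fraction = 0.5) {
  if (avg_rr <= 0) stop("avg_rr must be positive")
  if (amp_fraction <= 0) stop("amp_fraction must be positive")
  n <- length(x)
  if (n < 3) return(numeric(0))
  thr <- amp_fraction * sqrt(mean(x^2))
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] > x[i + 1] & x[i] >= thr]
  if (!length(cand)) return(numeric(0))
  # minimum separation in samples; one sample of slack absorbs the
  # quantization of peak locations onto the sampling grid
  min_sep <- round(fs * 60 / avg_rr) - 1L
  # tallest-first greedy pruning; ties keep the earlier peak
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (idx in ord) {
    if (!length(kept) || all(abs(kept - idx) >= min_sep))
      kept <- c(kept, idx)
  }
  (sort(kept) - 1) / fs
}

#' Remove physiologically implausible peaks
#'
#' Automated stand-in for the manual inspection step of breath-by-breath
#' analysis: while any inter-peak interval implies an instantaneous RR
#' above `max_rr` breaths/min, the lower-amplitude peak of the offending
#' pair is dropped.
#'
#' @param peak_times sorted peak times, s.
#' @param x trace the peaks were detected on (for amplitude comparison).
#' @param fs sampling rate of `x`, Hz.
#' @param max_rr plausibility ceiling, breaths/min (default 90).
#' @return Filtered peak times.
#' @export
filter_implausible_peaks <- function(peak_times, x, fs, max_rr = 90) {
  min_int <- 60 / max_rr
  amp <- function(tt) x[pmin(length(x), pmax(1, round(tt * fs) + 1))]
  while (length(peak_times) >= 2) {
    d <- diff(peak_times)
    bad <- which(d < min_int)
    if (!length(bad)) break
    j <- bad[1]
    drop <- if (amp(peak_times[j]) < amp(peak_times[j + 1])) j else j + 1
    peak_times <- peak_times[-drop]
  }
  peak_times
}

#' Breath-by-breath rate series from inspiratory peaks
#'
#' Inter-breath intervals are the times elapsed between consecutive
#' inspiratory peaks and the per-breath rate is `60 / interval`, so `N`
#' peaks yield `N - 1` rates.
#'
#' @param peak_times sorted inspiratory peak times, s (>= 2 peaks).
#' @return An object of class `"breath_series"`: list with `peak_times`
#'   (s), `intervals` (s) and `rates` (breaths/min).
#' @examples
#' breath_series(c(0, 4, 8, 12))$rates  # 15 15 15
#' @export
breath_series <- function(peak_times) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) < 2)
    stop("at least 2 peaks are needed for a breath-by-breath series")
  if (any(diff(peak_times) <= 0))
    stop("peak times must be strictly increasing")
  intervals <- diff(peak_times)
  structure(list(peak_times = peak_times, intervals = intervals,
                 rates = 60 / intervals),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf(
    "Breath series: %d breaths, RR %.2f +/- %.2f breaths/min\n",
    length(x$rates), mean(x$rates), sd(x$rates)))
  invisible(x)
}
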