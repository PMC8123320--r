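#' Welch power spectral density estimate
#'
#' Welch's overlapped segment averaging estimator: the trace is split
#' into overlapping segments, each is tapered with the chosen window,
#' zero-padded and transformed, and the one-sided modified periodograms
#' are averaged. Zero padding interpolates the spectrum onto a grid fine
#' enough that sub-breath/beat-per-minute rates are representable
#' (`freq_res`, default 0.005 Hz = 0.3 min^-1); it does not add true
#' resolution beyond the segment length.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param segment_s segment length, seconds (default 60). An error is
#'   raised if the trace is shorter than one segment.
#' @param overlap fractional overlap between segments (default 0.5).
#' @param window taper: `"hamming"` (default) or `"hann"`.
#' @param freq_res target frequency-grid spacing, Hz (via zero padding).
#' @return An object of class `"rate_spectrum"`: list with `freq` (Hz,
#'   starting at 0), `psd` (power/Hz, non-negative, one-sided) and
#'   `params`.
#' @examples
#' t <- seq(0, 180, by = 0.01)
#' sp <- welch_psd(sin(2 * pi * 0.3 * t), fs = 100)
#' sp$freq[which.max(sp$psd)]  # ~0.3 Hz
#' @export
welch_psd <- function(x, fs, segment_s = 60, overlap = 0.5,
                      window = c("hamming", "hann"), freq_res = 0.005) {
  window <- match.arg(window)
  n <- length(x)
  L <- round(segment_s * fs)
  if (L > n)
    stop("trace (", n, " samples) shorter than one Welch segment (",
         L, " samples)")
  if (L < 8) stop("Welch segment too short")
  w <- if (window == "hamming") as.numeric(signal::hamming(L))
       else as.numeric(signal::hanning(L))
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = hop)
  nfft <- max(L, round(fs / freq_res))
  nh <- nfft %/% 2 + 1L
  scale <- fs * sum(w^2)
  acc <- numeric(nh)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)] * w
    X <- fft(c(seg, numeric(nfft - L)))
    P <- (Mod(X[seq_len(nh)])^2) / scale
    # one-sided: double every bin except DC (and Nyquist for even nfft)
    last_doubled <- if (nfft %% 2 == 0) nh - 1L else nh
    if (last_doubled >= 2) P[2:last_doubled] <- 2 * P[2:last_doubled]
    acc <- acc + P
  }
  structure(list(
    freq = (seq_len(nh) - 1L) * fs / nfft,
    psd = acc / length(starts),
    params = list(segment_s = segment_s, window = window,
                  overlap = overlap, nfft = nfft, fs = fs,
                  n_segments = length(starts))
  ), class = "rate_spectrum")
}

#' @export
print.rate_spectrum <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Welch PSD: %d segments of %g s (%s, %.0f%% overlap), grid %.4g Hz\n",
    p$n_segments, p$segment_s, p$window, 100 * p$overlap,
    x$freq[2] - x$freq[1]))
  cat(sprintf("  peak %.4g Hz\n", x$freq[which.max(x$psd)]))
  invisible(x)
}

#' @export
plot.rate_spectrum <- function(x, band = NULL, xlim = NULL, ...) {
  plot(x$freq, x$psd, type = "l", xlab = "Frequency [Hz]",
       ylab = "PSD [power/Hz]", xlim = xlim, ...)
  if (!is.null(band)) abline(v = band, lty = 2, col = "grey40")
  invisible(x)
}

# Dominant in-band spectral peak; ties (and the plateau of a flat but
# non-zero band) resolve toward the lower frequency via which.max.
peak_frequency <- function(spec, band) {
  stopifnot(inherits(spec, "rate_spectrum"))
  if (max(spec$freq) < band[2] - 1e-9)
    stop("spectrum grid does not cover the ", band[1], "-", band[2],
         " Hz search band")
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  p <- spec$psd[sel]
  if (!any(is.finite(p)) || max(p, na.rm = TRUE) <= 0)
    stop("no dominant spectral peak in the ", band[1], "-", band[2],
         " Hz band (flat zero spectrum)")
  spec$freq[sel][which.max(p)]
}

#' Respiratory rate from a spectrum
#'
#' RR is 60 times the frequency of the highest PSD peak inside the
#' respiratory search band (default 0.1–1.5 Hz); ties break toward the
#' lower frequency. A flat zero in-band spectrum is an error.
#'
#' @param spec a [welch_psd()] result.
#' @param band search band, Hz.
#' @return RR in breaths/min.
#' @export
rr_from_spectrum <- function(spec, band = c(0.1, 1.5)) {
  60 * peak_frequency(spec, band)
}

#' Heart rate from a spectrum
#'
#' HR is 60 times the frequency of the highest PSD peak inside the
#' cardiac search band (default 0.7–4 Hz); ties break toward the lower
#' frequency. No harmonic correction is applied: if an envelope harmonic
#' outgrows the fundamental, the harmonic is returned (a known failure
#' mode of highest-peak selection under heavy motion artifact).
#'
#' @param spec a [welch_psd()] result.
#' @param band search band, Hz.
#' @return HR in beats/min.
#' @export
hr_from_spectrum <- function(spec, band = c(0.7, 4)) {
  60 * peak_frequency(spec, band)
}
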