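#' Band-pass filter specification
#'
#' A Butterworth band-pass design applied forward-backward (zero phase).
#' The design order is the order *before* the two-pass application, so a
#' `order = 3` specification reproduces the conventional
#' "third-order Butterworth + filtfilt" route: the effective magnitude
#' response is the square of the 3rd-order design and the net phase is
#' zero.
#'
#' Defaults used throughout the pipeline: 0.05–2 Hz for respiratory
#' conditioning, 0.7–20 Hz for the seismo/gyrocardiographic carrier and
#' 0.7–5 Hz for the final heart-beat envelope.
#'
#' @param low_hz,high_hz band edges, Hz; `0 <= low_hz < high_hz`.
#' @param order Butterworth design order (default 3).
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(low_hz, high_hz, order = 3) {
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("require 0 <= low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Butterworth band-pass %g-%g Hz, order %d, zero-phase\n",
              x$low_hz, x$high_hz, x$order))
  invisible(x)
}

#' Zero-phase band-pass filtering
#'
#' Applies the designed Butterworth band-pass forward and backward
#' (`filtfilt`), so the output has no phase distortion: peaks of
#' band-limited inputs are not displaced. Output length equals input
#' length. Edge transients of roughly the filter's settling time remain
#' at the two ends; downstream analyses exclude the first and last 5 s
#' from amplitude assertions for this reason.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param spec a [filter_spec()]; `high_hz` must be below `fs / 2`.
#' @return Filtered trace, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_hz >= fs / 2)
    stop("high_hz (", spec$high_hz, " Hz) must be below the Nyquist ",
         "frequency ", fs / 2, " Hz")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Fuse the four strain channels into one respiratory signal
#'
#' The pointwise arithmetic mean of the four conductive-channel voltages,
#' the fused respiratory signal the RR analyses operate on.
#'
#' @param channels an `n x 4` matrix or a list of four equal-length
#'   traces.
#' @return Numeric trace of length `n`.
#' @export
fuse_strain_channels <- function(channels) {
  if (is.list(channels) && !is.data.frame(channels)) {
    lens <- lengths(channels)
    if (length(unique(lens)) != 1)
      stop("strain channels must have equal length")
    channels <- do.call(cbind, channels)
  }
  channels <- as.matrix(channels)
  if (ncol(channels) != 4) stop("expected 4 strain channels")
  rowMeans(channels)
}

# Analytic signal via the FFT construction: negative frequencies zeroed,
# positive doubled, DC (and Nyquist for even n) kept.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope via the Hilbert transform
#'
#' Magnitude of the analytic signal,
#' `h(t) = sqrt(Re(s_hat)^2 + Im(s_hat)^2)`: for an amplitude-modulated
#' carrier `m(t) cos(2 pi f0 t)` whose modulator spectrum lies below f0,
#' the envelope recovers `|m(t)|` (AM demodulation). The envelope is
#' non-negative and invariant to a sign flip of the input.
#'
#' @param x finite numeric trace, length >= 16.
#' @return Non-negative envelope trace, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  if (length(x) < 16) stop("trace too short for envelope estimation")
  if (any(!is.finite(x))) stop("non-finite samples in input trace")
  Mod(analytic_signal(x))
}

#' Heart-beat envelope of a cardiac channel
#'
#' The cardiac demodulation chain: band-pass 0.7–20 Hz (removes bias,
#' breathing-related motion and high-frequency noise while keeping the
#' seismo/gyrocardiographic carrier), Hilbert envelope, then band-pass
#' 0.7–5 Hz to remove the envelope's bias and leave the heart-beat
#' envelope. The output may oscillate around zero (the final stage
#' removes the mean).
#'
#' @param x cardiac channel trace (accelerometer x, gyroscope x, or ECG).
#' @param fs sampling rate, Hz (>= 50).
#' @param carrier_band,envelope_band band edges, Hz, of the two stages.
#' @param order Butterworth design order for both stages.
#' @return Numeric trace, same length as `x`.
#' @export
cardiac_envelope <- function(x, fs, carrier_band = c(0.7, 20),
                             envelope_band = c(0.7, 5), order = 3) {
  if (fs < 50) stop("cardiac envelope extraction requires fs >= 50 Hz")
  s <- bandpass_zero_phase(x, fs, filter_spec(carrier_band[1],
                                              carrier_band[2], order))
  h <- hilbert_envelope(s)
  bandpass_zero_phase(h, fs, filter_spec(envelope_band[1],
                                         envelope_band[2], order))
}
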