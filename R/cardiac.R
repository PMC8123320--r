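# Sample indices of the analysis segment on a given clock.
segment_idx <- function(rec, fs) {
  (round(rec$analysis_segment[1] * fs) + 1):round(rec$analysis_segment[2] * fs)
}

# Processed cardiac trace for a given source: the heart-beat envelope for
# the IMU axes, the 0.7-20 Hz band-passed ECG (optionally also
# envelope-processed) for the reference. Conditioning is applied to the
# full recording and the analysis segment cut afterwards, so filter edge
# transients stay outside the segment.
cardiac_source_trace <- function(rec, source = c("gx", "ax", "ref"),
                                 carrier_band = c(0.7, 20),
                                 envelope_band = c(0.7, 5),
                                 order = 3, ref_envelope = FALSE) {
  source <- match.arg(source)
  if (source == "ref") {
    fs <- rec$fs_ecg
    x <- if (ref_envelope) {
      cardiac_envelope(rec$ref_ecg, fs, carrier_band, envelope_band, order)
    } else {
      bandpass_zero_phase(rec$ref_ecg, fs,
                          filter_spec(carrier_band[1], carrier_band[2],
                                      order))
    }
  } else {
    fs <- rec$fs_ws
    x <- cardiac_envelope(rec$imu[, source], fs, carrier_band,
                          envelope_band, order)
  }
  list(x = x[segment_idx(rec, fs)], fs = fs)
}

#' Whole-trial heart rate from one cardiac source
#'
#' Estimates the average HR over the analysis segment: heart-beat
#' envelope extraction (accelerometer or gyroscope x-axis) or band-pass
#' conditioning (reference ECG), Welch PSD over the segment, and the
#' highest in-band spectral peak.
#'
#' @param rec a [trial_recording()].
#' @param source `"gx"` (gyroscope x, default), `"ax"` (accelerometer x)
#'   or `"ref"` (reference ECG).
#' @param hr_band cardiac search band, Hz.
#' @param segment_s,overlap,freq_res Welch parameters (see
#'   [welch_psd()]).
#' @param ref_envelope if `TRUE`, envelope-process the reference ECG the
#'   same way as the IMU channels instead of using its band-passed form.
#' @param order Butterworth design order for the conditioning stages.
#' @return HR in beats/min.
#' @export
whole_trial_hr <- function(rec, source = c("gx", "ax", "ref"),
                           hr_band = c(0.7, 4), segment_s = 60,
                           overlap = 0.5, freq_res = 0.005,
                           ref_envelope = FALSE, order = 3) {
  src <- cardiac_source_trace(rec, source, order = order,
                              ref_envelope = ref_envelope)
  sp <- welch_psd(src$x, src$fs, segment_s = segment_s, overlap = overlap,
                  freq_res = freq_res)
  hr_from_spectrum(sp, hr_band)
}

#' Short-time (windowed) heart-rate series
#'
#' Slides a window (default 30 s, 50 % overlap, i.e. hop 15 s) over the
#' processed cardiac trace of the analysis segment and computes one HR
#' per window from the Hamming-tapered periodogram of that window,
#' zero-padded to a 0.1 beats/min grid. A 180 s segment yields 11
#' windows starting at 0, 15, ..., 150 s.
#'
#' @inheritParams whole_trial_hr
#' @param window_s window length, seconds (default 30; segment must be at
#'   least this long).
#' @param overlap fractional window overlap (default 0.5).
#' @param freq_res spectral grid spacing, Hz (default 0.1 beats/min).
#' @return An object of class `"windowed_hr"`: list with `window_starts`
#'   (s, relative to the analysis segment), `hr` (beats/min per window),
#'   `window_s`, `overlap` and `source`.
#' @export
windowed_hr <- function(rec, source = c("gx", "ax", "ref"),
                        window_s = 30, overlap = 0.5,
                        hr_band = c(0.7, 4), freq_res = 0.1 / 60,
                        ref_envelope = FALSE, order = 3) {
  source <- match.arg(source)
  src <- cardiac_source_trace(rec, source, order = order,
                              ref_envelope = ref_envelope)
  fs <- src$fs
  L <- round(window_s * fs)
  n <- length(src$x)
  if (L > n) stop("analysis segment shorter than one ", window_s,
                  " s window")
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = hop)
  hr <- vapply(starts, function(s0) {
    win <- src$x[s0:(s0 + L - 1L)]
    sp <- welch_psd(win, fs, segment_s = window_s, overlap = 0,
                    freq_res = freq_res)
    hr_from_spectrum(sp, hr_band)
  }, numeric(1))
  structure(list(window_starts = (starts - 1L) / fs, hr = hr,
                 window_s = window_s, overlap = overlap,
                 source = source),
            class = "windowed_hr")
}

#' @export
print.windowed_hr <- function(x, ...) {
  cat(sprintf(
    "Windowed HR (%s): %d windows of %g s, HR %.1f +/- %.1f beats/min\n",
    x$source, length(x$hr), x$window_s, mean(x$hr), sd(x$hr)))
  invisible(x)
}

#' @export
plot.windowed_hr <- function(x, ...) {
  plot(x$window_starts, x$hr, type = "b", xlab = "Window start [s]",
       ylab = "HR [beats/min]", ...)
  invisible(x)
}
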