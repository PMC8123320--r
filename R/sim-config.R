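#' Simulation configuration for synthetic chest-worn-sensor trials
#'
#' Bundles every tunable of the synthetic trial generator. Defaults
#' reproduce the acquisition protocol the analysis assumes: a 200 s trial
#' (10 s end-inspiration apnea, 180 s self-paced breathing, 10 s apnea),
#' wearable channels at 100 Hz, a reference respiratory waveform at 25 Hz
#' and a single-lead ECG at 250 Hz.
#'
#' @param scenario posture preset: `"sitting"`, `"standing"` or
#'   `"supine"`. Controls the default motion-artifact level on the
#'   accelerometer channel (standing > sitting > supine).
#' @param duration_s trial length in seconds (default 200).
#' @param fs_ws wearable-system sampling rate, Hz (strain + IMU; 100).
#' @param fs_ref_resp reference respiratory waveform rate, Hz (25).
#' @param fs_ecg reference ECG rate, Hz (250).
#' @param mean_rr mean respiratory rate, breaths/min. Must lie inside the
#'   0.1–1.5 Hz respiratory search band (6–90 breaths/min).
#' @param rr_wander_sd standard deviation of the slow respiratory-rate
#'   drift, breaths/min.
#' @param mean_hr mean heart rate, beats/min. Must lie inside the 0.7–4 Hz
#'   cardiac search band (42–240 beats/min).
#' @param hr_wander_sd standard deviation of the slow heart-rate drift,
#'   beats/min.
#' @param carrier_freq heartbeat carrier frequency f0, Hz. Must lie
#'   strictly inside the 0.7–20 Hz seismocardiographic band so the
#'   carrier survives band-pass conditioning; default 10 Hz sits well
#'   above the 5 Hz envelope cut-off.
#' @param strain_offset,strain_depth baseline strain and peak-to-trough
#'   breathing excursion of the thoracic band, in % strain. Their sum must
#'   not exceed the 10 % calibration domain.
#' @param abd_depth_ratio,abd_phase_lag abdominal band depth relative to
#'   the thoracic band, and its phase lag in radians.
#' @param noise_sd_strain additive white noise on each strain-channel
#'   voltage, in voltage units.
#' @param noise_sd_imu additive white noise on each IMU channel.
#' @param breathing_leakage amplitude of residual breathing motion on the
#'   cardiac IMU channels, as a fraction of the cardiac-signal RMS.
#' @param motion_artifact_level low-frequency body-motion artifact
#'   amplitude on the accelerometer x-axis, as a multiple of the cardiac
#'   RMS. `NULL` picks the scenario preset (supine 0.3, sitting 1.5,
#'   standing 8 — body sway while standing dwarfs the milli-g-scale
#'   seismocardiographic signal).
#' @param drift_amp,drift_freq amplitude (voltage units) and frequency
#'   (Hz) of the sinusoidal baseline drift added to the strain channels.
#'   `drift_freq` must stay below the 0.05 Hz respiratory high-pass
#'   cut-off so the drift is removable by design.
#' @param apnea_s duration of each breath-hold bracketing the trial, s.
#' @param seed integer seed; identical configurations (seed included)
#'   produce bit-identical trials.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @seealso [make_trial()]
#' @examples
#' cfg <- sim_config(scenario = "supine", mean_rr = 12, seed = 7)
#' cfg$motion_artifact_level
#' @export
sim_config <- function(scenario = c("sitting", "standing", "supine"),
                       duration_s = 200,
                       fs_ws = 100, fs_ref_resp = 25, fs_ecg = 250,
                       mean_rr = 15, rr_wander_sd = 0.5,
                       mean_hr = 70, hr_wander_sd = 1,
                       carrier_freq = 10,
                       strain_offset = 2, strain_depth = 4,
                       abd_depth_ratio = 0.8, abd_phase_lag = 0.15,
                       noise_sd_strain = 0.3, noise_sd_imu = 0.1,
                       breathing_leakage = 0.1,
                       motion_artifact_level = NULL,
                       drift_amp = 2, drift_freq = 0.02,
                       apnea_s = 10, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(motion_artifact_level)) {
    motion_artifact_level <- switch(scenario,
      supine = 0.3, sitting = 1.5, standing = 8)
  }
  cfg <- list(
    scenario = scenario, duration_s = duration_s,
    fs_ws = fs_ws, fs_ref_resp = fs_ref_resp, fs_ecg = fs_ecg,
    mean_rr = mean_rr, rr_wander_sd = rr_wander_sd,
    mean_hr = mean_hr, hr_wander_sd = hr_wander_sd,
    carrier_freq = carrier_freq,
    strain_offset = strain_offset, strain_depth = strain_depth,
    abd_depth_ratio = abd_depth_ratio, abd_phase_lag = abd_phase_lag,
    noise_sd_strain = noise_sd_strain, noise_sd_imu = noise_sd_imu,
    breathing_leakage = breathing_leakage,
    motion_artifact_level = motion_artifact_level,
    drift_amp = drift_amp, drift_freq = drift_freq,
    apnea_s = apnea_s, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$duration_s > 0, cfg$fs_ws > 0, cfg$fs_ref_resp > 0,
            cfg$fs_ecg > 0, cfg$apnea_s >= 0)
  if (cfg$duration_s <= 2 * cfg$apnea_s)
    stop("duration_s must exceed the two apnea holds (2 * apnea_s)")
  if (cfg$mean_rr / 60 < 0.1 || cfg$mean_rr / 60 > 1.5)
    stop("mean_rr must lie inside the respiratory search band ",
         "(0.1-1.5 Hz, i.e. 6-90 breaths/min)")
  if (cfg$mean_hr / 60 < 0.7 || cfg$mean_hr / 60 > 4)
    stop("mean_hr must lie inside the cardiac search band ",
         "(0.7-4 Hz, i.e. 42-240 beats/min)")
  if (cfg$carrier_freq <= 0.7 || cfg$carrier_freq >= 20)
    stop("carrier_freq (f0) must lie strictly inside the 0.7-20 Hz band; ",
         "outside it the carrier is destroyed by band-pass conditioning")
  if (cfg$drift_freq >= 0.05)
    stop("drift_freq must stay below 0.05 Hz (the respiratory high-pass ",
         "cut-off) so baseline drift is removable by design")
  if (cfg$strain_offset < 0 || cfg$strain_depth < 0 ||
      cfg$strain_offset + cfg$strain_depth > 10)
    stop("strain_offset + strain_depth exceeds the 10 % strain ",
         "calibration domain; the sensor model is only valid on [0, 10] %")
  if (cfg$rr_wander_sd < 0 || cfg$hr_wander_sd < 0 ||
      cfg$noise_sd_strain < 0 || cfg$noise_sd_imu < 0)
    stop("noise and wander standard deviations must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic trial configuration\n")
  cat(sprintf("  scenario: %s   duration: %g s (apnea %g s each end)\n",
              x$scenario, x$duration_s, x$apnea_s))
  cat(sprintf("  rates: WS %g Hz, ref resp %g Hz, ECG %g Hz\n",
              x$fs_ws, x$fs_ref_resp, x$fs_ecg))
  cat(sprintf("  RR %g +/- %g breaths/min, HR %g +/- %g beats/min, f0 %g Hz\n",
              x$mean_rr, x$rr_wander_sd, x$mean_hr, x$hr_wander_sd,
              x$carrier_freq))
  cat(sprintf("  motion artifact %g x cardiac RMS, seed %d\n",
              x$motion_artifact_level, x$seed))
  invisible(x)
}

# Deterministic per-operation substream so individual generator stages can
# be called on their own and still be reproducible from config$seed.
sim_seed <- function(cfg, stage) {
  offsets <- c(breathing = 1L, beats = 2L, imu = 3L, reference = 4L,
               voltage = 5L)
  (abs(cfg$seed) %% 1000003L) * 1009L + offsets[[stage]]
}

# Smooth slowly-drifting rate profile (breaths/min or beats/min) on a time
# grid: random walk at 10 s knots, centred, scaled to `wander_sd`, spline
# interpolated. wander_sd = 0 gives a constant profile.
rate_profile <- function(t, mean_rate, wander_sd, lo, hi) {
  if (wander_sd <= 0) return(rep(mean_rate, length(t)))
  knots <- seq(0, max(t), by = 10)
  if (length(knots) < 4) knots <- seq(0, max(t), length.out = 4)
  w <- cumsum(rnorm(length(knots)))
  w <- w - mean(w)
  s <- sd(w)
  if (s > 0) w <- w / s * wander_sd
  prof <- mean_rate + spline(knots, w, xout = t)$y
  pmin(pmax(prof, lo), hi)
}
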