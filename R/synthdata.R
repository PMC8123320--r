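#' Simulate rib-cage breathing strain with known breath peaks
#'
#' Generates quasi-sinusoidal thoracic and abdominal strain traces on the
#' wearable-system clock. The breathing phase advances at the (slowly
#' drifting) instantaneous respiratory rate; during the two breath-hold
#' intervals the strain is held at its end-inspiration value, so the trial
#' reproduces the apnea / 3-min breathing / apnea protocol shape.
#'
#' The strain model is `offset + depth * (1 - cos(phi(t))) / 2` with
#' `dphi/dt = 2 * pi * rr(t) / 60`, so end-inspiration peaks fall at
#' `phi = pi (mod 2*pi)`. The two bands share the rate profile but differ
#' in depth and a small phase lag.
#'
#' @param config a [sim_config()] object.
#' @return A list with components
#'   * `t` — time grid, s;
#'   * `thoracic`, `abdominal` — strain traces, % strain, within \[0, 10\];
#'   * `breath_peak_times` — ground-truth end-inspiration instants, s
#'     (strictly inside the breathing segment);
#'   * `rr_profile` — instantaneous respiratory rate on the WS clock,
#'     breaths/min;
#'   * `apnea_intervals` — two-column matrix of (start, end) s.
#' @examples
#' br <- simulate_breathing_strain(sim_config(mean_rr = 12, seed = 3))
#' range(br$thoracic)
#' @export
simulate_breathing_strain <- function(config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "breathing"))
  fs <- config$fs_ws
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  t0 <- config$apnea_s
  t1 <- config$duration_s - config$apnea_s

  rr <- rate_profile(t, config$mean_rr, config$rr_wander_sd, lo = 6, hi = 30)

  # Phase: held at the end-inspiration value (pi) during both apneas;
  # integrated over the breathing segment and rescaled so it ends exactly
  # on a peak (the final breath-hold starts at end-inspiration).
  breathing <- t >= t0 & t <= t1
  dphi <- ifelse(breathing, 2 * pi * rr / 60 / fs, 0)
  phi_raw <- cumsum(dphi)
  total <- phi_raw[n]
  k_cycles <- max(1L, round(total / (2 * pi)))
  scale <- (2 * pi * k_cycles) / total
  phi <- pi + phi_raw * scale

  thoracic <- config$strain_offset +
    config$strain_depth * (1 - cos(phi)) / 2
  phi_abd <- ifelse(breathing & t > t0, phi - config$abd_phase_lag, phi)
  abdominal <- config$strain_offset +
    config$strain_depth * config$abd_depth_ratio * (1 - cos(phi_abd)) / 2

  # Breath peaks: phi crossing pi + 2*pi*k, k = 1..k_cycles, located by
  # linear interpolation of the phase restricted to the breathing segment
  # (where it is strictly increasing).
  targets <- pi + 2 * pi * seq_len(k_cycles)
  ib <- which(dphi > 0)
  ib <- c(min(ib) - 1L, ib)
  peaks <- approx(phi[ib], t[ib], xout = targets, ties = "ordered")$y
  peaks <- peaks[is.finite(peaks)]
  peaks <- peaks[peaks > t0 & peaks <= t1 + 1e-6]

  list(t = t, thoracic = thoracic, abdominal = abdominal,
       breath_peak_times = peaks, rr_profile = rr,
       apnea_intervals = rbind(c(0, t0), c(t1, config$duration_s)))
}

#' Strain-to-voltage calibration curve of the conductive textile sensors
#'
#' Quasi-static calibration of the conductive-textile sensing elements
#' (strain applied up to 10 %, output taken after the bridge and
#' amplification stage): a second-order polynomial
#' `y(x) = 0.12 x^2 - 3.81 x + 59.97` with `x` in % strain. The curve is
#' strictly decreasing on the calibration domain (vertex at x = 15.875),
#' so inspiration (strain increase) lowers the output voltage.
#'
#' @param x strain, % (each value must lie in \[0, 10\]).
#' @return Sensor output in voltage-like arbitrary units.
#' @examples
#' calibration_curve(0)    # 59.97
#' calibration_curve(10)   # 33.87
#' @export
calibration_curve <- function(x) {
  if (any(!is.finite(x)) || any(x < 0 | x > 10))
    stop("strain outside the [0, 10] % calibration domain: ",
         "the sensor model must not be extrapolated")
  0.12 * x^2 - 3.81 * x + 59.97
}

#' Transduce band strains into the four sensor-channel voltages
#'
#' Applies the [calibration_curve()] to the thoracic and abdominal strain
#' traces (two sensors per band, four channels total), then adds
#' independent white measurement noise and a slow sinusoidal baseline
#' drift per channel.
#'
#' @param strain a list with `thoracic` and `abdominal` traces (% strain)
#'   as returned by [simulate_breathing_strain()], or a single numeric
#'   trace used for all four channels.
#' @param config a [sim_config()] object (noise and drift settings).
#' @return An `n x 4` matrix, columns `ch1`, `ch2` (thoracic) and `ch3`,
#'   `ch4` (abdominal), voltage-like units.
#' @export
strain_to_voltage <- function(strain, config) {
  validate_sim_config(config)
  if (is.numeric(strain)) strain <- list(thoracic = strain, abdominal = strain)
  set.seed(sim_seed(config, "voltage"))
  n <- length(strain$thoracic)
  t <- (seq_len(n) - 1) / config$fs_ws
  band <- list(strain$thoracic, strain$thoracic,
               strain$abdominal, strain$abdominal)
  out <- vapply(seq_len(4), function(k) {
    y <- calibration_curve(band[[k]])
    drift_phase <- runif(1, 0, 2 * pi)
    y + rnorm(n, 0, config$noise_sd_strain) +
      config$drift_amp * sin(2 * pi * config$drift_freq * t + drift_phase)
  }, numeric(n))
  colnames(out) <- paste0("ch", 1:4)
  out
}

#' Simulate heartbeat times with a slowly drifting rate
#'
#' Beat instants are generated by integrating the instantaneous cardiac
#' phase at the (slowly drifting) heart-rate profile; successive gaps
#' equal 60 / HR evaluated at the gap midpoint to within the drift's
#' slow-variation error.
#'
#' @param config a [sim_config()] object.
#' @return A list with `beat_times` (s, strictly increasing over the full
#'   trial) and `hr_profile` (beats/min on the WS clock).
#' @export
simulate_beat_times <- function(config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "beats"))
  fs <- config$fs_ws
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  hr <- rate_profile(t, config$mean_hr, config$hr_wander_sd,
                     lo = 42, hi = 240)
  psi <- cumsum(hr / 60 / fs)  # beats elapsed
  k <- seq_len(floor(psi[n]))
  beats <- approx(psi, t, xout = k, ties = "ordered")$y
  beats <- beats[is.finite(beats)]
  list(beat_times = beats, hr_profile = hr)
}

#' Simulate the cardiac IMU channels (seismo/gyrocardiography)
#'
#' Builds the amplitude-modulated heartbeat model `s(t) = h(t) cos(2 pi
#' f0 t) + eps(t)`: `h(t)` is a train of unit-area Gaussian bumps (50 ms
#' width) centred on the beat instants, so the envelope's dominant
#' spectral rate equals the beat rate. The gyroscope x-axis carries the
#' clean model plus breathing leakage and white noise; the accelerometer
#' x-axis additionally carries a scenario-scaled low-frequency
#' body-motion artifact (standing > sitting > supine), reflecting the
#' accelerometer's higher sensitivity to body motion. The remaining seven
#' IMU channels are placeholder noise, present only for format fidelity.
#'
#' @param config a [sim_config()] object.
#' @param beat_times heartbeat instants, s, within \[0, duration\].
#' @param breathing optional breathing trace on the WS clock used for the
#'   leakage term (e.g. the thoracic strain); `NULL` disables leakage.
#' @return A list with `ax`, `gx` (numeric traces) and `other` (an
#'   `n x 7` matrix: `ay, az, gy, gz, mx, my, mz`).
#' @export
simulate_cardiac_imu <- function(config, beat_times, breathing = NULL) {
  validate_sim_config(config)
  if (length(beat_times) &&
      (min(beat_times) < 0 || max(beat_times) > config$duration_s))
    stop("beat_times must lie within [0, duration_s]")
  set.seed(sim_seed(config, "imu"))
  fs <- config$fs_ws
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  h <- gaussian_pulse_train(t, beat_times, width = 0.05, fs = fs)
  carrier <- cos(2 * pi * config$carrier_freq * t)
  cardiac <- h * carrier
  c_rms <- sqrt(mean(cardiac^2))

  leak <- numeric(n)
  if (!is.null(breathing) && config$breathing_leakage > 0) {
    b <- breathing - mean(breathing)
    b_sd <- sd(b)
    if (b_sd > 0) leak <- config$breathing_leakage * c_rms * b / b_sd
  }

  gx <- cardiac + leak + rnorm(n, 0, config$noise_sd_imu)

  artifact <- numeric(n)
  if (config$motion_artifact_level > 0) {
    artifact <- motion_artifact(n, fs) *
      config$motion_artifact_level * c_rms
  }
  ax <- cardiac + leak + artifact + rnorm(n, 0, config$noise_sd_imu)

  other <- matrix(rnorm(n * 7, 0, config$noise_sd_imu), ncol = 7)
  colnames(other) <- c("ay", "az", "gy", "gz", "mx", "my", "mz")
  list(ax = ax, gx = gx, other = other)
}

# Unit-area Gaussian bump train; only +/- 5 sd of support is filled in.
gaussian_pulse_train <- function(t, centers, width, fs) {
  n <- length(t)
  h <- numeric(n)
  half <- ceiling(5 * width * fs)
  for (b in centers) {
    i0 <- max(1L, floor(b * fs) - half)
    i1 <- min(n, floor(b * fs) + half)
    idx <- i0:i1
    h[idx] <- h[idx] + dnorm(t[idx], mean = b, sd = width)
  }
  h
}

# Low-frequency body-motion artifact: white noise band-limited to
# 0.3-6 Hz (inside the seismocardiographic pass-band, so it corrupts the
# envelope), normalised to unit RMS.
motion_artifact <- function(n, fs) {
  x <- rnorm(n)
  bf <- signal::butter(2, c(0.3, 6) / (fs / 2), type = "pass")
  a <- signal::filtfilt(bf, x)
  a / sqrt(mean(a^2))
}

#' Simulate the reference-system recordings
#'
#' The reference device is modelled as given signals: an ECG-like trace
#' (narrow Gaussian pulse at each beat instant plus white noise — R-peak
#' timing only, no P/T-wave morphology) at `fs_ecg`, and a reference
#' respiratory waveform (the thoracic band strain resampled to
#' `fs_ref_resp` plus independent noise).
#'
#' @param config a [sim_config()] object.
#' @param beat_times heartbeat instants, s.
#' @param breathing_strain thoracic strain trace on the WS clock.
#' @param noise_sd_resp white-noise sd added to the resampled respiratory
#'   waveform (% strain units).
#' @return A list with `ecg` (at `fs_ecg`) and `resp` (at `fs_ref_resp`).
#' @export
simulate_reference <- function(config, beat_times, breathing_strain,
                               noise_sd_resp = 0.05) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "reference"))
  n_e <- round(config$duration_s * config$fs_ecg)
  t_e <- (seq_len(n_e) - 1) / config$fs_ecg
  ecg <- gaussian_pulse_train(t_e, beat_times, width = 0.02,
                              fs = config$fs_ecg)
  ecg <- ecg / max(ecg) + rnorm(n_e, 0, 0.02)

  n_r <- round(config$duration_s * config$fs_ref_resp)
  t_r <- (seq_len(n_r) - 1) / config$fs_ref_resp
  t_ws <- (seq_len(length(breathing_strain)) - 1) / config$fs_ws
  resp <- approx(t_ws, breathing_strain, xout = t_r, rule = 2)$y +
    rnorm(n_r, 0, noise_sd_resp)
  list(ecg = ecg, resp = resp)
}

#' Generate one complete synthetic trial with ground truth
#'
#' Bundles the breathing, sensor-calibration, cardiac-IMU and
#' reference-system generators into a [trial_recording()] plus the
#' matching ground truth. Identical configurations (seed included) give
#' bit-identical output.
#'
#' @param config a [sim_config()] object.
#' @return A list with components `recording` (class `trial_recording`)
#'   and `truth` (class `ground_truth`; fields `breath_peak_times`,
#'   `beat_times`, `rr_profile`, `hr_profile`, `apnea_intervals`,
#'   `mean_rr`, `mean_hr`).
#' @examples
#' trial <- make_trial(sim_config(seed = 11))
#' trial$recording
#' length(trial$truth$breath_peak_times)
#' @export
make_trial <- function(config = sim_config()) {
  validate_sim_config(config)
  br <- simulate_breathing_strain(config)
  volts <- strain_to_voltage(br, config)
  beats <- simulate_beat_times(config)
  imu <- simulate_cardiac_imu(config, beats$beat_times,
                              breathing = br$thoracic)
  ref <- simulate_reference(config, beats$beat_times, br$thoracic)

  imu_mat <- cbind(ax = imu$ax, imu$other[, c("ay", "az")],
                   gx = imu$gx, imu$other[, c("gy", "gz")],
                   imu$other[, c("mx", "my", "mz")])
  rec <- trial_recording(
    scenario = config$scenario,
    strain = volts, imu = imu_mat,
    ref_resp = ref$resp, ref_ecg = ref$ecg,
    fs_ws = config$fs_ws, fs_ref_resp = config$fs_ref_resp,
    fs_ecg = config$fs_ecg,
    analysis_segment = c(config$apnea_s,
                         config$duration_s - config$apnea_s),
    seed = config$seed
  )

  seg <- rec$analysis_segment
  in_seg <- br$t >= seg[1] & br$t <= seg[2]
  truth <- structure(list(
    breath_peak_times = br$breath_peak_times,
    beat_times = beats$beat_times,
    rr_profile = br$rr_profile,
    hr_profile = beats$hr_profile,
    apnea_intervals = br$apnea_intervals,
    mean_rr = mean(br$rr_profile[in_seg]),
    mean_hr = mean(beats$hr_profile[in_seg])
  ), class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$breath_peak_times), "breaths,",
      length(x$beat_times), "beats\n")
  cat(sprintf("  mean RR %.2f breaths/min, mean HR %.2f beats/min\n",
              x$mean_rr, x$mean_hr))
  invisible(x)
}
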