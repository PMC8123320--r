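test_that("strain-to-voltage calibration matches the quasi-static curve", {
  expect_equal(calibration_curve(0), 59.97)
  expect_equal(calibration_curve(10), 0.12 * 100 - 3.81 * 10 + 59.97)
  expect_equal(calibration_curve(10), 33.87)
  x <- seq(0, 10, by = 0.01)
  expect_true(all(diff(calibration_curve(x)) < 0))
  expect_error(calibration_curve(10.5), "calibration domain")
  expect_error(calibration_curve(-0.1), "calibration domain")
})

test_that("breathing generator reproduces the protocol shape", {
  cfg <- sim_config(mean_rr = 15, rr_wander_sd = 0, seed = 42)
  br <- simulate_breathing_strain(cfg)
  # 15 breaths/min x 3 min of breathing = 45 cycles
  expect_equal(length(br$breath_peak_times), 45)
  expect_true(all(br$breath_peak_times > 10))
  expect_true(all(br$breath_peak_times <= 190 + 1e-6))
  expect_true(all(diff(br$breath_peak_times) > 0))
  expect_true(all(br$thoracic >= 0 & br$thoracic <= 10))
  # strain held at end-inspiration (offset + depth) during both apneas
  t <- br$t
  hold <- cfg$strain_offset + cfg$strain_depth
  expect_equal(br$thoracic[t < 10], rep(hold, sum(t < 10)))
  expect_equal(br$thoracic[t > 190], rep(hold, sum(t > 190)),
               tolerance = 1e-6)
})

test_that("generated breath timing recovers the configured rate", {
  br <- simulate_breathing_strain(
    sim_config(mean_rr = 12, rr_wander_sd = 0.5, seed = 7))
  rates <- 60 / diff(br$breath_peak_times)
  expect_lt(abs(mean(rates) - 12), 0.5)
})

test_that("strain exceeding the calibration domain is rejected", {
  expect_error(sim_config(strain_offset = 4, strain_depth = 7),
               "10 % strain")
})

test_that("noiseless breathing strain places its spectral peak at mean_rr", {
  cfg <- sim_config(mean_rr = 15, rr_wander_sd = 0, noise_sd_strain = 0,
                    drift_amp = 0, seed = 3)
  br <- simulate_breathing_strain(cfg)
  seg <- br$t >= 10 & br$t <= 190
  f <- oracle_dft_peak(br$thoracic[seg], cfg$fs_ws, c(0.1, 1.5))
  expect_lt(abs(f - 15 / 60), 1 / 180 + 1e-9)  # one DFT grid bin
})

test_that("cardiac IMU model demodulates to the beat rate", {
  cfg <- sim_config(mean_hr = 60, hr_wander_sd = 0, noise_sd_imu = 0,
                    motion_artifact_level = 0, breathing_leakage = 0,
                    seed = 5)
  beats <- seq(0.5, 199.5, by = 1)  # exactly 60 beats/min
  imu <- simulate_cardiac_imu(cfg, beats)
  env <- cardiac_envelope(imu$gx, cfg$fs_ws)
  sp <- welch_psd(env[1001:19000], cfg$fs_ws)
  pk <- sp$freq[which.max(sp$psd)]
  expect_lt(abs(pk - 1.0), 0.005 + 1e-9)
  # oracle cross-check on the raw envelope
  f_oracle <- oracle_dft_peak(env[1001:19000], cfg$fs_ws, c(0.7, 4))
  expect_lt(abs(f_oracle - 1.0), 1 / 180 + 1e-9)
})

test_that("carrier frequencies outside the SCG band are rejected", {
  expect_error(sim_config(carrier_freq = 0.5), "0.7-20")
  expect_error(sim_config(carrier_freq = 25), "0.7-20")
})

test_that("motion artifact increases from supine to standing", {
  lv <- vapply(c("supine", "sitting", "standing"),
               function(s) sim_config(scenario = s)$motion_artifact_level,
               numeric(1))
  expect_true(lv[["supine"]] < lv[["sitting"]])
  expect_true(lv[["sitting"]] < lv[["standing"]])
})

test_that("beat times follow the instantaneous heart-rate profile", {
  cfg <- sim_config(mean_hr = 72, hr_wander_sd = 2, seed = 11)
  b <- simulate_beat_times(cfg)
  expect_true(all(diff(b$beat_times) > 0))
  gaps <- diff(b$beat_times)
  mids <- (b$beat_times[-1] + b$beat_times[-length(b$beat_times)]) / 2
  hr_at_mid <- approx((seq_along(b$hr_profile) - 1) / cfg$fs_ws,
                      b$hr_profile, xout = mids)$y
  expect_true(all(abs(gaps - 60 / hr_at_mid) / (60 / hr_at_mid) < 0.05))
})

test_that("reference streams have the declared shape and content", {
  cfg <- sim_config(seed = 13)
  br <- simulate_breathing_strain(cfg)
  beats <- simulate_beat_times(cfg)$beat_times
  ref <- simulate_reference(cfg, beats, br$thoracic)
  expect_equal(length(ref$resp), round(cfg$duration_s * 25))
  expect_equal(length(ref$ecg), round(cfg$duration_s * 250))
  expect_equal(oracle_count_pulses(ref$ecg), length(beats))
})

test_that("noise-free reference respiration peaks at mean_rr after filtering", {
  cfg <- sim_config(mean_rr = 15, rr_wander_sd = 0, seed = 17)
  br <- simulate_breathing_strain(cfg)
  beats <- simulate_beat_times(cfg)$beat_times
  ref <- simulate_reference(cfg, beats, br$thoracic, noise_sd_resp = 0)
  filt <- bandpass_zero_phase(ref$resp, cfg$fs_ref_resp,
                              filter_spec(0.05, 2))
  seg <- filt[(10 * 25 + 1):(190 * 25)]
  f <- oracle_dft_peak(seg, cfg$fs_ref_resp, c(0.1, 1.5))
  expect_lt(abs(f - 0.25), 1 / 180 + 1e-9)
})

test_that("make_trial bundles all streams at the declared rates", {
  trial <- make_trial(sim_config(seed = 19))
  rec <- trial$recording
  expect_s3_class(rec, "trial_recording")
  expect_equal(ncol(rec$strain), 4)
  expect_equal(ncol(rec$imu), 9)
  expect_equal(colnames(rec$imu),
               c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz"))
  expect_equal(nrow(rec$strain), 20000)
  expect_equal(length(rec$ref_resp), 5000)
  expect_equal(length(rec$ref_ecg), 50000)
  expect_equal(rec$analysis_segment, c(10, 190))
  # no ground-truth breath peak inside the apnea holds
  expect_false(any(trial$truth$breath_peak_times < 10))
  expect_false(any(trial$truth$breath_peak_times > 190 + 1e-6))
})

test_that("trials are reproducible from the seed and differ across seeds", {
  a <- make_trial(sim_config(seed = 23))
  b <- make_trial(sim_config(seed = 23))
  c <- make_trial(sim_config(seed = 24))
  expect_identical(a, b)
  expect_false(identical(a$recording$strain, c$recording$strain))
  expect_false(identical(a$recording$imu[, "gx"], c$recording$imu[, "gx"]))
})
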