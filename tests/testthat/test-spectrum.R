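test_that("Welch PSD locates a sinusoid at its true frequency", {
  fs <- 100
  t <- seq(0, 180 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.3 * t)
  sp <- welch_psd(x, fs)
  expect_s3_class(sp, "rate_spectrum")
  expect_true(all(sp$psd >= 0))
  expect_true(all(diff(sp$freq) > 0))
  expect_equal(sp$freq[1], 0)
  pk <- sp$freq[which.max(sp$psd)]
  expect_lt(abs(pk - oracle_dft_peak(x, fs, c(0.05, 2))), 0.005 + 1e-9)
  expect_lt(abs(pk - 0.3), 0.005 + 1e-9)
})

test_that("white-noise PSD integrates to the trace variance", {
  set.seed(4)
  fs <- 100
  x <- rnorm(fs * 180)
  sp <- welch_psd(x, fs)
  # trapezoid over the one-sided spectrum approximates var(x)
  area <- sum(diff(sp$freq) * (head(sp$psd, -1) + tail(sp$psd, -1)) / 2)
  expect_lt(abs(area - var(x)) / var(x), 0.10)
})

test_that("peak PSD scales with signal power", {
  fs <- 100
  t <- seq(0, 180, by = 1 / fs)
  x <- sin(2 * pi * 0.3 * t)
  p1 <- max(welch_psd(x, fs)$psd)
  p2 <- max(welch_psd(2 * x, fs)$psd)
  expect_equal(p2 / p1, 4, tolerance = 1e-6)
})

test_that("a segment longer than the trace is an error", {
  expect_error(welch_psd(rnorm(100), 100, segment_s = 60),
               "shorter than one Welch segment")
})

test_that("RR picks the highest in-band spectral peak", {
  # synthetic breathing at 15 breaths/min, zero noise
  cfg <- sim_config(mean_rr = 15, rr_wander_sd = 0, noise_sd_strain = 0,
                    drift_amp = 0, seed = 6)
  br <- simulate_breathing_strain(cfg)
  seg <- br$t >= 10 & br$t <= 190
  x <- bandpass_zero_phase(br$thoracic, cfg$fs_ws, filter_spec(0.05, 2))
  rr <- rr_from_spectrum(welch_psd(x[seg], cfg$fs_ws))
  expect_lt(abs(rr - 15), 0.3 + 1e-9)  # one 0.005 Hz grid bin in bpm

  # hand-built spectra: band restriction and tie-breaking
  grid <- seq(0, 2, by = 0.005)
  single <- structure(list(freq = grid,
                           psd = as.numeric(grid == 0.2),
                           params = list()), class = "rate_spectrum")
  expect_equal(rr_from_spectrum(single), 12.0)

  two <- structure(list(freq = grid,
                        psd = 0.4 * (grid == 0.25) + 1.0 * (grid == 1.8),
                        params = list()), class = "rate_spectrum")
  expect_equal(rr_from_spectrum(two), 15.0)  # 1.8 Hz is out of band

  flat <- structure(list(freq = grid, psd = numeric(length(grid)),
                         params = list()), class = "rate_spectrum")
  expect_error(rr_from_spectrum(flat), "no dominant spectral peak")
})

test_that("HR picks the highest in-band peak and rejects empty bands", {
  grid <- seq(0, 5, by = 0.005)
  single <- structure(list(freq = grid,
                           psd = as.numeric(grid == 1.0),
                           params = list()), class = "rate_spectrum")
  expect_equal(hr_from_spectrum(single), 60.0)

  below <- structure(list(freq = grid,
                          psd = as.numeric(grid == 0.5),
                          params = list()), class = "rate_spectrum")
  expect_error(hr_from_spectrum(below), "no dominant spectral peak")

  short_grid <- structure(list(freq = seq(0, 2, by = 0.01),
                               psd = rep(1, 201), params = list()),
                          class = "rate_spectrum")
  expect_error(hr_from_spectrum(short_grid), "does not cover")
})

test_that("envelope of a simulated 72 beats/min trial yields 72", {
  cfg <- sim_config(mean_hr = 72, hr_wander_sd = 0, noise_sd_imu = 0.02,
                    motion_artifact_level = 0, seed = 8)
  trial <- make_trial(cfg)
  hr <- whole_trial_hr(trial$recording, "gx")
  expect_lt(abs(hr - 72), 0.3 + 1e-9)
})
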