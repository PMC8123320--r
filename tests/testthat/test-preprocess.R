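fs <- 100
t <- seq(0, 200, by = 1 / fs)
mid <- t > 50 & t < 150  # central half, away from filter edge transients

test_that("zero-phase band-pass rejects DC and passes the breathing band", {
  spec <- filter_spec(0.05, 2)
  dc <- bandpass_zero_phase(rep(5, length(t)), fs, spec)
  expect_lt(max(abs(dc[mid])), 1e-3 * 5)

  tone <- sin(2 * pi * 0.25 * t)
  out <- bandpass_zero_phase(tone, fs, spec)
  expect_lt(abs(max(abs(out[mid])) - 1), 0.02)
})

test_that("filtering is zero-phase: a symmetric pulse peak does not move", {
  pulse <- exp(-((t - 100)^2) / (2 * 4^2))
  out <- bandpass_zero_phase(pulse, fs, filter_spec(0.01, 2))
  expect_lte(abs(which.max(out) - which.max(pulse)), 1)

  # cross-correlation lag between band-limited input and output is zero
  tone <- sin(2 * pi * 0.3 * t)
  out <- bandpass_zero_phase(tone, fs, filter_spec(0.05, 2))
  cc <- ccf(out[mid], tone[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band edges above Nyquist are rejected", {
  expect_error(bandpass_zero_phase(t, 25, filter_spec(0.7, 20)), "Nyquist")
  expect_error(filter_spec(2, 1), "low_hz < high_hz")
})

test_that("channel fusion is the pointwise mean of the four channels", {
  x <- sin(2 * pi * 0.2 * t)
  expect_equal(fuse_strain_channels(cbind(x, x, x, x)), x)
  const <- cbind(rep(1, 10), rep(2, 10), rep(3, 10), rep(4, 10))
  expect_equal(fuse_strain_channels(const), rep(2.5, 10))

  set.seed(1)
  m <- matrix(rnorm(400), ncol = 4)
  manual <- vapply(seq_len(100), function(i) mean(m[i, ]), numeric(1))
  expect_equal(fuse_strain_channels(m), manual)
  expect_error(fuse_strain_channels(list(1:5, 1:5, 1:5, 1:4)),
               "equal length")
  expect_error(fuse_strain_channels(m[, 1:3]), "4 strain channels")
})

test_that("Hilbert envelope recovers tone amplitude and AM modulators", {
  A <- 2.7
  tone <- A * cos(2 * pi * 10 * t)
  env <- hilbert_envelope(tone)
  expect_true(all(abs(env[mid] - A) / A < 0.01))

  mod <- 1 + 0.5 * cos(2 * pi * 1 * t)
  am <- mod * cos(2 * pi * 10 * t)
  env <- hilbert_envelope(am)
  rms_err <- sqrt(mean((env[mid] - mod[mid])^2)) / sqrt(mean(mod[mid]^2))
  expect_lt(rms_err, 0.03)

  expect_equal(hilbert_envelope(-am), hilbert_envelope(am))
  expect_true(all(hilbert_envelope(am) >= 0))
  expect_error(hilbert_envelope(c(1, 2, NA, 4, rep(0, 12))), "non-finite")
  expect_error(hilbert_envelope(1:8), "too short")
})

test_that("cardiac envelope demodulates an AM heartbeat signal", {
  cfg <- sim_config(mean_hr = 60, hr_wander_sd = 0, noise_sd_imu = 0,
                    motion_artifact_level = 0, breathing_leakage = 0,
                    seed = 2)
  beats <- seq(0.5, 199.5, by = 1)
  s <- simulate_cardiac_imu(cfg, beats)$gx
  env <- cardiac_envelope(s, fs)
  f <- oracle_dft_peak(env[mid], fs, c(0.7, 4))
  expect_lt(abs(f - 1.0), 1 / 100 + 1e-9)

  # constant-envelope carrier: nothing left after the 0.7 Hz high-pass
  carrier <- cos(2 * pi * 10 * t)
  out <- cardiac_envelope(carrier, fs)
  expect_lt(max(abs(out[mid])), 1e-2)

  # amplitude linearity through the chain
  out1 <- cardiac_envelope(s, fs)
  out2 <- cardiac_envelope(2 * s, fs)
  expect_equal(out2[mid], 2 * out1[mid], tolerance = 1e-8)
})

test_that("envelope demodulation recovers randomized modulators", {
  set.seed(99)
  for (k in 1:8) {
    f0 <- runif(1, 6, 18)
    fm <- runif(1, 0.7, 2)
    depth <- runif(1, 0.2, 0.8)
    mod <- 1 + depth * cos(2 * pi * fm * t)
    env <- hilbert_envelope(mod * cos(2 * pi * f0 * t))
    rms_err <- sqrt(mean((env[mid] - mod[mid])^2)) /
      sqrt(mean(mod[mid]^2))
    expect_lt(rms_err, 0.03)
  }
})
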