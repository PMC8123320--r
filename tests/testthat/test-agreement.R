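test_that("absolute and percentage errors follow their definitions", {
  expect_equal(absolute_error(12, 12), 0)
  expect_equal(absolute_error(15, 14.99), 0.01)
  expect_equal(absolute_error(3, 7), absolute_error(7, 3))
  expect_equal(percentage_error(20, 19), 5)
  expect_equal(percentage_error(7, 7), 0)
  expect_equal(percentage_error(8, 6.4), percentage_error(16, 12.8))
  expect_error(percentage_error(0, 1), "non-positive")
  expect_error(absolute_error(NA, 1), "finite")
})

test_that("breath pairing matches peaks and drops spurious detections", {
  ref <- breath_series(c(0, 4, 8, 12, 16))
  ws_same <- breath_series(c(0, 4, 8, 12, 16))
  p <- pair_breaths(ref, ws_same)
  expect_equal(p$ref_rates, rep(15, 4))
  expect_equal(p$ws_rates, rep(15, 4))
  expect_equal(p$n_unmatched_ws, 0)

  # uniform +0.2 s shift is well inside the half-median-interval tolerance
  ws_shift <- breath_series(c(0, 4, 8, 12, 16) + 0.2)
  p <- pair_breaths(ref, ws_shift)
  expect_length(p$ref_rates, 4)
  expect_equal(p$ws_rates, rep(15, 4))

  # hand-traced greedy rule: one spurious extra WS peak mid-interval.
  # Exact matches (distance 0) claim their partners first, the 6 s peak
  # finds every reference peak taken, so it stays unmatched and the rate
  # pairs still span each of the 4 reference breaths.
  ws_spur <- breath_series(c(0, 4, 6, 8, 12, 16))
  p <- pair_breaths(ref, ws_spur)
  expect_equal(p$n_unmatched_ws, 1)
  expect_length(p$ref_rates, 4)
  expect_equal(p$ws_rates, rep(15, 4))

  # no overlap at all
  far <- breath_series(c(100, 104, 108))
  expect_error(pair_breaths(ref, far), "no matched breath pairs")
})

test_that("a missed wearable breath drops that interval from the pairs", {
  ref <- breath_series(c(0, 4, 8, 12, 16))
  ws_missing <- breath_series(c(0, 4, 12, 16))  # 8 s peak undetected
  p <- pair_breaths(ref, ws_missing)
  # intervals 4-8 and 8-12 are dropped; 0-4 and 12-16 survive
  expect_equal(p$ref_rates, c(15, 15))
  expect_equal(p$n_unmatched_ref, 1)
})

test_that("MAE matches hand arithmetic and a brute-force loop", {
  expect_equal(mae(list(ref_rates = c(15, 15, 15),
                        ws_rates = c(15, 15, 15))),
               list(mae = 0, mae_pct = 0))
  out <- mae(list(ref_rates = c(10, 20), ws_rates = c(11, 18)))
  expect_equal(out$mae, 1.5)
  expect_equal(out$mae_pct, 10)

  set.seed(21)
  r <- runif(50, 10, 20); w <- r + rnorm(50)
  out <- mae(list(ref_rates = r, ws_rates = w))
  s_abs <- 0; s_pct <- 0
  for (i in seq_along(r)) {
    s_abs <- s_abs + abs(r[i] - w[i])
    s_pct <- s_pct + 100 * abs(r[i] - w[i]) / r[i]
  }
  expect_equal(out$mae, s_abs / 50)
  expect_equal(out$mae_pct, s_pct / 50)
})

test_that("Bland-Altman statistics follow the MOD/LOA construction", {
  same <- bland_altman(c(12, 14, 16), c(12, 14, 16))
  expect_equal(same$mod, 0)
  expect_equal(same$loa_upper, 0)
  expect_equal(same$loa_lower, 0)

  shifted <- bland_altman(c(10, 12, 14), c(10, 12, 14) - 2)
  expect_equal(shifted$mod, 2)
  expect_equal(shifted$sd_differences, 0)
  expect_equal(shifted$loa_upper, 2)
  expect_equal(shifted$loa_lower, 2)

  # hand computation, sample (n-1) standard deviation convention
  ba <- bland_altman(c(10, 12, 14), c(11, 11, 15))
  expect_equal(ba$differences, c(-1, 1, -1))
  expect_equal(ba$mod, -1 / 3)
  s <- sqrt(sum((c(-1, 1, -1) + 1 / 3)^2) / 2)
  expect_equal(ba$sd_differences, s)
  expect_equal(ba$loa_upper, -1 / 3 + 1.96 * s)
  expect_equal(ba$loa_lower, -1 / 3 - 1.96 * s)
  expect_equal(ba$means, c(10.5, 11.5, 14.5))
  expect_error(bland_altman(1, 2), "at least 2 pairs")
})

test_that("LOA identity holds on arbitrary inputs", {
  set.seed(33)
  for (k in 1:10) {
    n <- sample(3:50, 1)
    ba <- bland_altman(runif(n, 8, 25), runif(n, 8, 25))
    expect_equal(ba$loa_upper - ba$loa_lower,
                 2 * 1.96 * ba$sd_differences)
    expect_equal((ba$loa_upper + ba$loa_lower) / 2, ba$mod)
    expect_equal(ba$mod, mean(ba$differences))
  }
})

test_that("aggregation reproduces scenario averages", {
  one <- aggregate_report(data.frame(subject = 1, scenario = "sitting",
                                     value = 0.42))
  expect_equal(one$sitting, c(0.42, 0.42))

  tabs <- study_error_tables()
  rr <- aggregate_report(tabs$rr_abs)
  expect_equal(nrow(rr), 9)  # 8 subjects + Average
  avg <- as.data.frame(rr)[9, ]
  expect_equal(avg$sitting, mean(tabs$rr_abs$value[1:8]))
  # spot-check the printed columns
  expect_equal(round(avg$sitting, 2), 0.17)
  hr <- as.data.frame(aggregate_report(tabs$hr_gx))
  expect_equal(round(hr[9, "standing"], 2), 3.81)
})

test_that("MAE is bounded by the worst pair and zero only at equality", {
  set.seed(44)
  r <- runif(30, 10, 20); w <- r + rnorm(30, sd = 0.5)
  out <- mae(list(ref_rates = r, ws_rates = w))
  expect_gte(out$mae, 0)
  expect_lte(out$mae, max(abs(r - w)))
  expect_gt(out$mae, 0)
})
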