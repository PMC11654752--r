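test_that("pulse segmentation matches an independent extrema scan", {
  tr <- synth_ppg(60, 6, 100)
  pulses <- segment_pulses(tr, smooth_window_s = 0, refine_troughs = FALSE)
  expect_s3_class(pulses, "pulse_feature")
  expect_gte(nrow(pulses), 5L)
  expect_lte(nrow(pulses), 6L)
  expect_true(all(pulses$i_max > pulses$i_min))

  # oracle: naive amplitude-gated local-minimum scan on the raw samples
  oracle <- brute_force_troughs(tr)
  troughs <- attr(pulses, "trough_times_s")
  expect_equal(length(troughs), length(oracle), tolerance = 1)
  matched <- vapply(troughs, function(t) min(abs(oracle / 100 - t)), numeric(1))
  expect_lt(max(matched), 0.05)
})

test_that("segmentation enforces trough ordering and separation", {
  tr <- synth_ppg(90, 10, 200)
  pulses <- segment_pulses(tr, hr_min_bpm = 40, hr_max_bpm = 220)
  troughs <- attr(pulses, "trough_times_s")
  expect_true(all(diff(troughs) > 0))
  expect_true(all(diff(troughs) >= 60 / 220))
  expect_true(all(diff(pulses$t_min) >= 60 / 220))
})

test_that("segmentation rejects degenerate traces", {
  expect_error(segment_pulses(signal_trace(rep(1, 500), 100)), "constant")
  expect_error(segment_pulses(signal_trace(rep(0, 500), 100)), "positive")
  short <- synth_ppg(60, 1, 100)
  expect_error(segment_pulses(short, hr_min_bpm = 40), "shorter")
})

test_that("pulse_r computes the log ratio-of-ratios", {
  p <- function(imax, imin) list(i_max = imax, i_min = imin)
  # identical modulation on both channels
  expect_equal(pulse_r(p(1, 0.93), p(1, 0.93)), 1.0)
  # depths 13% and 7%: ln(1/0.87) / ln(1/0.93)
  expect_equal(pulse_r(p(1, 0.87), p(1, 0.93)),
               log(1 / 0.87) / log(1 / 0.93))
  expect_equal(pulse_r(p(1, 0.87), p(1, 0.93)), 1.919, tolerance = 1e-3)
  # scale invariance in either channel
  expect_equal(pulse_r(p(5, 5 * 0.87), p(0.2, 0.2 * 0.93)),
               pulse_r(p(1, 0.87), p(1, 0.93)))
  expect_error(pulse_r(p(1, 0.9), p(1, 1)), "i_max > i_min")
})

test_that("the linear calibration matches its published anchor points", {
  r <- r_from_spo2(c(86, 90, 95, 100))
  expect_equal(round(r, 2), c(1.12, 0.96, 0.76, 0.55))
  expect_equal(spo2_from_r(0), 113.8)
  expect_equal(spo2_from_r(0.55), 100.1215)
  expect_equal(r_from_spo2(113.8), 0)
  # strictly decreasing in R
  rs <- seq(0, 2, by = 0.1)
  expect_true(all(diff(spo2_from_r(rs)) < 0))
  expect_error(spo2_from_r(-0.1), ">= 0")
  expect_error(r_from_spo2(120), "<=")
})

test_that("spo2_from_r and r_from_spo2 are exact inverses", {
  s <- seq(86, 100, by = 0.5)
  expect_equal(spo2_from_r(r_from_spo2(s)), s, tolerance = 1e-12)
})

test_that("depth_for_spo2 solves the R-ratio design equation", {
  # R = 1 at SpO2 = 113.8 - 24.87: equal depths
  s_unity <- 113.8 - 24.87
  expect_equal(depth_for_spo2(s_unity, 0.07), 0.07, tolerance = 1e-12)

  # oracle: numeric root-solve of the R definition for d660
  for (case in list(c(86, 0.07), c(90, 0.05), c(95, 0.12), c(100, 0.07))) {
    spo2 <- case[1]; d940 <- case[2]
    r_target <- r_from_spo2(spo2)
    root <- stats::uniroot(function(d660) {
      log(1 / (1 - d660)) / log(1 / (1 - d940)) - r_target
    }, c(1e-6, 0.9), tol = 1e-12)$root
    expect_equal(depth_for_spo2(spo2, d940), root, tolerance = 1e-9)
  }
  expect_equal(depth_for_spo2(86, 0.07), 0.078, tolerance = 1e-3 / 0.078)

  # strictly decreasing in SpO2 at fixed 940 nm depth
  depths <- vapply(seq(86, 100, by = 2), depth_for_spo2, numeric(1),
                   depth_940 = 0.07)
  expect_true(all(diff(depths) < 0))
  expect_error(suppressWarnings(depth_for_spo2(-2000, 0.99)), "unreachable")
})

test_that("estimate_spo2 recovers programmed saturation in a noiseless loop", {
  ph <- fixture_phantom()
  lut660 <- fixture_lut(660, ph); lut940 <- fixture_lut(940, ph)
  ppg <- resample_trace(max_normalize(synth_ppg(75, 6, 1000)), 50)
  d940 <- 0.07
  for (level in c(90, 95)) {
    d660 <- depth_for_spo2(level, d940)
    m660 <- measure_intensity(
      quantize_dac(map_signal(lut660, scale_to_depth(ppg, d660)), ph$dac_step_v),
      get_channel_for_test(ph, 660), ph)
    m940 <- measure_intensity(
      quantize_dac(map_signal(lut940, scale_to_depth(ppg, d940)), ph$dac_step_v),
      get_channel_for_test(ph, 940), ph)
    est <- estimate_spo2(m660, m940)
    expect_s3_class(est, "oximetry_estimate")
    expect_equal(est$spo2, level, tolerance = 0.5 / level)
    expect_equal(est$r_mean, mean(est$per_pulse_r))
    expect_gte(est$n_pulses, 5L)
  }
})

test_that("identical channels give R = 1 and the R = 1 saturation", {
  tr <- scale_to_depth(max_normalize(synth_ppg(75, 6, 50)), 0.05)
  est <- estimate_spo2(tr, tr)
  expect_equal(est$r_mean, 1, tolerance = 1e-9)
  expect_equal(est$spo2, 113.8 - 24.87, tolerance = 1e-9)
})

test_that("per-pulse R of an exactly periodic signal is constant", {
  ppg <- max_normalize(synth_ppg(80, 6, 200))
  t660 <- scale_to_depth(ppg, 0.10)
  t940 <- scale_to_depth(ppg, 0.07)
  est <- estimate_spo2(t660, t940)
  expect_lt(diff(range(est$per_pulse_r)), 1e-9)
})

test_that("estimate_spo2 validates channel compatibility", {
  a <- scale_to_depth(max_normalize(synth_ppg(75, 6, 50)), 0.05)
  b <- scale_to_depth(max_normalize(synth_ppg(75, 6, 100)), 0.05)
  expect_error(estimate_spo2(a, b), "sampling rates")
  c2 <- scale_to_depth(max_normalize(synth_ppg(75, 3, 50)), 0.05)
  expect_error(estimate_spo2(a, c2), "durations")
})
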