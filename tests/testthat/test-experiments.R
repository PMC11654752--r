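test_that("percentage_error measures mean absolute normalized deviation", {
  tr <- max_normalize(synth_ppg(75, 2, 100))
  same <- percentage_error(tr, tr)
  expect_equal(same$average_error_percent, 0)
  expect_equal(max(same$error_trace$values), 0)

  shifted <- trace_like_for_test(tr, tr$values + 0.01)
  suppressWarnings({
    res <- percentage_error(tr, shifted)
    expect_equal(res$average_error_percent, 1.0)
    # symmetric in its arguments
    expect_equal(percentage_error(shifted, tr)$average_error_percent,
                 res$average_error_percent)
  })
  expect_warning(percentage_error(tr, shifted), "max-normalized")
  other <- max_normalize(synth_ppg(75, 2, 50))
  expect_error(percentage_error(tr, other), "length")
})

test_that("fit_line reproduces hand-computed least squares", {
  exact <- suppressWarnings(fit_line(1:10, 2 * (1:10) + 1)) # lm flags perfect fits
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  # three points by hand: slope 1.5, r^2 = 1 - (1/6)/(14/3)
  f <- fit_line(c(1, 2, 3), c(1, 2, 4))
  expect_equal(f$slope, 1.5)
  expect_equal(f$r_squared, 1 - (1 / 6) / (14 / 3))
  expect_equal(f$r_squared, 0.964, tolerance = 1e-3)
  expect_equal(f$n_points, 3L)

  # r^2 invariant under affine rescaling of y
  y <- c(1, 2, 4)
  expect_equal(fit_line(c(1, 2, 3), 10 * y - 3)$r_squared, f$r_squared)

  expect_error(fit_line(c(1, 1, 1), y), "constant")
  expect_error(fit_line(1:2, 1:2), "3 points")
})

test_that("recover_heart_rate inverts the mean trough interval", {
  expect_equal(recover_heart_rate(synth_ppg(60, 6, 100)), 60, tolerance = 0.01)
  expect_error(recover_heart_rate(signal_trace(rep(1, 1000), 100)), "constant")
})

test_that("closed-loop heart-rate recovery is accurate at 50 Hz", {
  ph <- fixture_phantom()
  lut <- fixture_lut(940, ph)
  ppg <- resample_trace(max_normalize(synth_ppg(100, 20, 1000)), 50)
  volts <- synthesize_modulation(lut, ppg, depth = 0.01,
                                 dac_step_v = ph$dac_step_v)
  measured <- measure_intensity(volts, get_channel_for_test(ph, 940), ph)
  expect_equal(recover_heart_rate(measured, hr_band = c(50, 180)), 100,
               tolerance = 1 / 100)
})

test_that("the heart-rate study covers the design grid and recovers rates", {
  ph <- fixture_phantom()
  study <- run_hr_study(ph, noise_sd = 0, seed = 1)
  expect_equal(nrow(study$rows), 20L) # 4 channels x 5 rates
  expect_setequal(unique(study$rows$wavelength_nm), c(940, 660, 530, 455))
  expect_true(all(study$rows$abs_error_bpm < 1))
  expect_length(study$regressions, 4L)
  for (reg in study$regressions) {
    expect_equal(reg$slope, 1, tolerance = 0.02)
    expect_gte(reg$r_squared, 0.999)
  }
})

test_that("study outputs are bit-identical under a fixed seed", {
  ph <- fixture_phantom()
  a <- run_hr_study(ph, rates_bpm = c(80, 100, 120), channels = 940,
                    duration_s = 10, noise_sd = 0.001, seed = 17)
  b <- run_hr_study(ph, rates_bpm = c(80, 100, 120), channels = 940,
                    duration_s = 10, noise_sd = 0.001, seed = 17)
  expect_identical(a$rows, b$rows)
  s1 <- run_spo2_study(ph, levels_percent = c(90, 95, 100), noise_sd = 1e-4,
                       seed = 23)
  s2 <- run_spo2_study(ph, levels_percent = c(90, 95, 100), noise_sd = 1e-4,
                       seed = 23)
  expect_identical(s1$rows, s2$rows)
})

test_that("the saturation study reproduces the calibration R ladder", {
  study <- run_spo2_study(fixture_phantom(), seed = 1)
  rows <- study$rows
  expect_equal(rows$spo2_programmed_percent, c(86, 90, 95, 100))
  expect_true(all(abs(rows$mean_r - rows$r_expected) < 0.01))
  expect_true(all(diff(rows$mean_r) < 0)) # R falls as saturation rises
  expect_true(all(abs(rows$spo2_recovered_percent -
                        rows$spo2_programmed_percent) < 0.5))
  expect_gte(study$regression$r_squared, 0.999)
  expect_gte(study$regression$slope, 0.98)
  expect_lte(study$regression$slope, 1.02)
})

test_that("noiseless fidelity is quantization-limited on every channel", {
  ph <- fixture_phantom()
  for (wl in c(940, 660, 530, 455)) {
    fid <- run_fidelity_check(ph, wl, depth = 0.01, noise_sd = 0, seed = 1)
    expect_lt(fid$average_error_percent, 0.01)
  }
})
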