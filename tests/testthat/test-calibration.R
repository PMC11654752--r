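test_that("sweep produces the expected grid and monotone in-band response", {
  ph <- fixture_phantom()
  curve <- sweep_channel(ph, 660)
  expect_s3_class(curve, "transfer_curve")
  expect_length(curve$voltages_v, 51L) # (3.0 - 0.5) / 0.05 + 1
  expect_equal(curve$voltages_v[1], 0.5)
  expect_equal(curve$voltages_v[51], 3.0)
  in_band <- curve$voltages_v >= 1.2 & curve$voltages_v <= 2.4
  expect_true(all(diff(curve$intensities[in_band]) < 0))
  expect_error(sweep_channel(ph, 800), "unknown channel")
})

test_that("repeat averaging shrinks sweep scatter about tenfold", {
  ph <- fixture_phantom()
  ph$detector_noise_sd <- 0.01
  truth <- sweep_channel(fixture_phantom(), 940)$intensities
  one <- sweep_channel(ph, 940, n_repeats = 1, seed = 21)$intensities
  hundred <- sweep_channel(ph, 940, n_repeats = 100, seed = 22)$intensities
  ratio <- stats::sd(one - truth) / stats::sd(hundred - truth)
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("functional-range detection recovers the fixture band", {
  ph <- fixture_phantom()
  for (wl in c(940, 660, 530, 455)) {
    band <- find_functional_range(sweep_channel(ph, wl))
    expect_equal(band[["v_lo"]], 1.2, tolerance = 0.05 / 1.2)
    expect_equal(band[["v_hi"]], 2.4, tolerance = 0.05 / 2.4)
  }
})

test_that("functional-range detection handles degenerate shapes", {
  v <- seq(0.5, 3, by = 0.1)
  dec <- transfer_curve(v, seq(1, 0.5, length.out = length(v)))
  band <- find_functional_range(dec)
  expect_equal(unname(band), c(0.5, 3))
  inc <- transfer_curve(v, seq(0.5, 1, length.out = length(v)))
  expect_error(find_functional_range(inc), "no functional range")
  expect_error(find_functional_range(transfer_curve(v, rep(1, length(v)))),
               "constant")
})

test_that("functional-range detection is invariant to intensity scaling", {
  curve <- sweep_channel(fixture_phantom(), 530)
  scaled <- transfer_curve(curve$voltages_v, curve$intensities * 37.5)
  expect_identical(find_functional_range(curve), find_functional_range(scaled))
})

test_that("build_lut normalizes, strictifies, and records depth", {
  ph <- fixture_phantom()
  for (wl in c(940, 660, 530, 455)) {
    lut <- build_lut(sweep_channel(ph, wl), 1.2, 2.4)
    expect_identical(lut$normalized_intensities[1], 1)
    expect_true(all(diff(lut$normalized_intensities) < 0))
    d_true <- get_channel_for_test(ph, wl)$depth_max
    expect_equal(lut$depth, d_true, tolerance = 0.005 / d_true)
  }
  expect_error(build_lut(sweep_channel(ph, 660), 1.2, 1.25), "band too narrow")
})

test_that("noisy sweeps still yield strictly monotone lookup tables", {
  ph <- fixture_phantom()
  ph$detector_noise_sd <- 0.005
  lut <- build_lut(sweep_channel(ph, 455, seed = 9), 1.2, 2.4)
  expect_true(all(diff(lut$normalized_intensities) < 0))
  expect_identical(lut$normalized_intensities[1], 1)
})

test_that("lookup tables are invariant to source intensity", {
  ph <- fixture_phantom()
  lut1 <- characterize_channel(ph, 660)
  ph$source_intensity <- 123.4
  lut2 <- characterize_channel(ph, 660)
  expect_equal(lut1$normalized_intensities, lut2$normalized_intensities,
               tolerance = 1e-12)
  expect_equal(lut1$voltages_v, lut2$voltages_v)
})

test_that("lut_invert interpolates, clamps with warnings, and is monotone", {
  lut <- fixture_lut(660)
  expect_equal(lut_invert(lut, 1.0), lut$v_lo)
  expect_equal(lut_invert(lut, 1 - lut$depth), lut$v_hi, tolerance = 1e-6)
  expect_warning(v_hi_clamp <- lut_invert(lut, 0.5), "clamped to v_hi")
  expect_equal(v_hi_clamp, lut$v_hi, tolerance = 1e-6)
  expect_warning(v_lo_clamp <- lut_invert(lut, 1.5), "clamped to v_lo")
  expect_equal(v_lo_clamp, lut$v_lo)

  targets <- seq(1 - lut$depth, 1, length.out = 200)
  volts <- lut_invert(lut, targets)
  expect_true(all(diff(volts) <= 0)) # larger target -> smaller voltage
})

test_that("lut_invert agrees with dense-grid brute-force inversion", {
  ph <- fixture_phantom()
  ch <- get_channel_for_test(ph, 660)
  lut <- fixture_lut(660, ph)
  targets <- seq(1 - lut$depth + 1e-6, 1, length.out = 100)
  volts <- lut_invert(lut, targets)
  # oracle: evaluate the channel forward model on the inverted voltages
  realized <- lcd_response(volts, ch) / lcd_response(lut$v_lo, ch)
  expect_lt(max(abs(realized - targets)), 1e-3)
  # oracle 2: nearest dense-grid voltage for each target
  dense_v <- seq(lut$v_lo, lut$v_hi, length.out = 50001)
  dense_y <- lcd_response(dense_v, ch) / lcd_response(lut$v_lo, ch)
  brute <- vapply(targets, function(t) dense_v[which.min(abs(dense_y - t))],
                  numeric(1))
  realized_brute <- lcd_response(brute, ch) / lcd_response(lut$v_lo, ch)
  expect_lt(max(abs(realized - targets)), max(abs(realized_brute - targets)) + 1e-3)
})

test_that("lookup tables survive a CSV round trip with sidecar metadata", {
  lut <- fixture_lut(940)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lut_csv(lut, path)
  back <- read_lut_csv(path)
  expect_equal(back$voltages_v, lut$voltages_v)
  expect_equal(back$normalized_intensities, lut$normalized_intensities)
  expect_equal(back$depth, lut$depth)
  expect_equal(back$channel, lut$channel)
})
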