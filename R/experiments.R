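#' Percentage error between normalized target and measured traces
#'
#' Per-sample absolute difference times 100 (percentage points of the
#' normalized scale), plus its arithmetic mean over samples. Both inputs are
#' expected max-normalized; a warning is drawn if either maximum strays from
#' 1. Symmetric in its arguments.
#'
#' @param target_norm,measured_norm Max-normalized [signal_trace()]s of equal
#'   length and sampling rate.
#' @return A list: `error_trace` (a [signal_trace()] in percent) and
#'   `average_error_percent`.
#' @export
percentage_error <- function(target_norm, measured_norm) {
  stopifnot(inherits(target_norm, "signal_trace"),
            inherits(measured_norm, "signal_trace"))
  if (length(target_norm$values) != length(measured_norm$values)) {
    stop("traces must have equal length", call. = FALSE)
  }
  if (target_norm$sampling_rate_hz != measured_norm$sampling_rate_hz) {
    stop("traces must have equal sampling rates", call. = FALSE)
  }
  if (abs(max(target_norm$values) - 1) > 1e-6 ||
      abs(max(measured_norm$values) - 1) > 1e-6) {
    warning("inputs do not look max-normalized (max != 1)", call. = FALSE)
  }
  err <- abs(measured_norm$values - target_norm$values) * 100
  list(
    error_trace = trace_like(target_norm, err, unit = "%", label = "pct error"),
    average_error_percent = mean(err)
  )
}

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric vectors, length >= 3; `x` must not be constant.
#' @return A list of class `regression_summary`: `slope`, `intercept`,
#'   `r_squared` (`1 - SS_res / SS_tot`), `n_points`.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` must not be constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = summary(fit)$r.squared,
         n_points = length(x)),
    class = "regression_summary"
  )
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("<regression_summary> y = %.4f x + %.4f, r^2 = %.6f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Recover heart rate from a pulsatile trace
#'
#' 60 divided by the mean trough-to-trough interval from [segment_pulses()].
#'
#' @param trace A [signal_trace()] containing at least two complete pulses.
#' @param hr_band Plausible heart-rate band `c(min, max)` in bpm.
#' @param ... Passed to [segment_pulses()].
#' @return Heart rate in bpm.
#' @export
recover_heart_rate <- function(trace, hr_band = c(40, 220), ...) {
  pulses <- segment_pulses(trace, hr_band[1], hr_band[2], ...)
  troughs <- attr(pulses, "trough_times_s")
  if (length(troughs) < 3L) {
    stop("need at least 2 complete pulses to recover a heart rate", call. = FALSE)
  }
  60 / mean(diff(troughs))
}

# Shared closed-loop signal path: normalized PPG -> modulation voltage ->
# detected intensity at the measurement rate.
closed_loop_measure <- function(phantom_meas, channel_nm, lut, target_norm,
                                depth, measure_rate_hz) {
  ch <- get_channel(phantom_meas, channel_nm)
  target <- resample_trace(target_norm, measure_rate_hz)
  volts <- synthesize_modulation(lut, target, depth = depth,
                                 dac_step_v = phantom_meas$dac_step_v)
  list(target = target,
       measured = measure_intensity(volts, ch, phantom_meas))
}

#' Heart-rate case study
#'
#' For each channel and programmed rate: synthesize a PPG record, push it
#' through the full closed loop (max normalization, resampling to the
#' measurement rate, depth scaling, lookup-table inversion, DAC quantization,
#' noisy detection), and recover the heart rate from the mean inter-trough
#' interval; then regress recovered on programmed rates per channel.
#'
#' Channels are characterized noiselessly (the phantom's configured noise)
#' before the study; `noise_sd` applies to the study measurements only.
#'
#' @param phantom A [phantom_config()]; defaults to [default_phantom()].
#' @param rates_bpm Programmed heart rates.
#' @param channels Wavelengths to run; default all channels of the phantom.
#' @param duration_s Record length in seconds.
#' @param synth_rate_hz Synthesis sampling rate in Hz.
#' @param measure_rate_hz Measurement sampling rate in Hz.
#' @param depth Modulation depth imposed on every channel (default 1%, a
#'   typical resting perfusion index every channel ceiling can express).
#' @param noise_sd Detector noise for the study measurements, as a fraction
#'   of source intensity.
#' @param hr_band Heart-rate band for pulse detection, bpm.
#' @param seed Integer seed; the whole study is bit-reproducible given it.
#' @return A list: `rows` (data frame: wavelength_nm, programmed_bpm,
#'   recovered_bpm, abs_error_bpm) and `regressions` (per-channel
#'   [fit_line()] summaries, named by wavelength).
#' @export
run_hr_study <- function(phantom = default_phantom(),
                         rates_bpm = c(80, 90, 100, 110, 120),
                         channels = NULL, duration_s = 20,
                         synth_rate_hz = 1000, measure_rate_hz = 50,
                         depth = 0.01, noise_sd = 0.001,
                         hr_band = c(50, 180), seed = NULL) {
  stopifnot(inherits(phantom, "phantom_config"))
  if (is.null(channels)) channels <- as.integer(names(phantom$channels))
  phantom_meas <- phantom
  phantom_meas$detector_noise_sd <- noise_sd

  with_seed(seed, {
    luts <- lapply(channels, function(wl) characterize_channel(phantom, wl))
    names(luts) <- as.character(channels)

    rows <- do.call(rbind, lapply(channels, function(wl) {
      do.call(rbind, lapply(rates_bpm, function(hr) {
        ppg <- max_normalize(synth_ppg(hr, duration_s, synth_rate_hz))
        loop <- closed_loop_measure(phantom_meas, wl, luts[[as.character(wl)]],
                                    ppg, depth, measure_rate_hz)
        rec <- recover_heart_rate(loop$measured, hr_band)
        data.frame(wavelength_nm = wl, programmed_bpm = hr,
                   recovered_bpm = rec, abs_error_bpm = abs(rec - hr))
      }))
    }))
    regressions <- lapply(split(rows, rows$wavelength_nm), function(df) {
      fit_line(df$programmed_bpm, df$recovered_bpm)
    })
    list(rows = rows, regressions = regressions)
  })
}

#' Oxygen-saturation case study
#'
#' One normalized PPG record drives both wavelengths. For each programmed
#' saturation level the 660 nm channel is scaled to the depth that realizes
#' the calibration R value against a fixed 940 nm depth
#' ([depth_for_spo2()]); both traces run through the closed loop, and
#' [estimate_spo2()] recovers the mean R and saturation.
#'
#' @param phantom A [phantom_config()] with 660 and 940 nm channels.
#' @param levels_percent Programmed SpO2 levels.
#' @param depth_940 Fixed 940 nm modulation depth.
#' @param duration_s,hr_bpm,synth_rate_hz,measure_rate_hz Record parameters
#'   of the shared synthetic PPG (default: 6 s at 75 bpm, synthesized at
#'   1000 Hz, measured at 50 Hz).
#' @param window_s R averaging window in seconds.
#' @param noise_sd Detector noise for the study measurements, fraction of
#'   source intensity.
#' @param hr_band Heart-rate band for pulse detection, bpm.
#' @param seed Integer seed; the whole study is bit-reproducible given it.
#' @return A list: `rows` (data frame: spo2_programmed_percent, depth_660,
#'   mean_r, r_expected, spo2_recovered_percent, n_pulses) and `regression`
#'   (recovered on programmed, a [fit_line()] summary).
#' @export
run_spo2_study <- function(phantom = default_phantom(),
                           levels_percent = c(86, 90, 95, 100),
                           depth_940 = 0.07, duration_s = 6, hr_bpm = 75,
                           synth_rate_hz = 1000, measure_rate_hz = 50,
                           window_s = 6, noise_sd = 0, hr_band = c(50, 180),
                           seed = NULL) {
  stopifnot(inherits(phantom, "phantom_config"))
  phantom_meas <- phantom
  phantom_meas$detector_noise_sd <- noise_sd

  with_seed(seed, {
    lut660 <- characterize_channel(phantom, 660)
    lut940 <- characterize_channel(phantom, 940)
    ppg <- max_normalize(synth_ppg(hr_bpm, duration_s, synth_rate_hz))

    rows <- do.call(rbind, lapply(levels_percent, function(level) {
      d660 <- depth_for_spo2(level, depth_940)
      loop660 <- closed_loop_measure(phantom_meas, 660, lut660, ppg, d660,
                                     measure_rate_hz)
      loop940 <- closed_loop_measure(phantom_meas, 940, lut940, ppg, depth_940,
                                     measure_rate_hz)
      est <- estimate_spo2(loop660$measured, loop940$measured,
                           window_s = window_s, hr_band = hr_band)
      data.frame(spo2_programmed_percent = level, depth_660 = d660,
                 mean_r = est$r_mean, r_expected = r_from_spo2(level),
                 spo2_recovered_percent = est$spo2, n_pulses = est$n_pulses)
    }))
    regression <- fit_line(rows$spo2_programmed_percent,
                           rows$spo2_recovered_percent)
    list(rows = rows, regression = regression)
  })
}

#' Closed-loop reconstruction fidelity for one channel
#'
#' Pushes a synthetic PPG through depth scaling, lookup-table inversion, DAC
#' quantization, and (optionally noisy) detection on one channel, then scores
#' the reconstruction with [percentage_error()] against the scaled target.
#'
#' @param phantom A [phantom_config()].
#' @param channel_nm Wavelength to evaluate.
#' @param depth Modulation depth to impose.
#' @param duration_s,hr_bpm,synth_rate_hz,measure_rate_hz Record parameters.
#' @param noise_sd Detector noise, fraction of source intensity.
#' @param seed Integer seed.
#' @return A list: `average_error_percent`, `error_trace`, `n_samples`.
#' @export
run_fidelity_check <- function(phantom = default_phantom(), channel_nm = 455,
                               depth = 0.01, duration_s = 6, hr_bpm = 75,
                               synth_rate_hz = 1000, measure_rate_hz = 50,
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_config"))
  phantom_meas <- phantom
  phantom_meas$detector_noise_sd <- noise_sd
  with_seed(seed, {
    lut <- characterize_channel(phantom, channel_nm)
    ppg <- max_normalize(synth_ppg(hr_bpm, duration_s, synth_rate_hz))
    loop <- closed_loop_measure(phantom_meas, channel_nm, lut, ppg, depth,
                                measure_rate_hz)
    target_scaled <- scale_to_depth(loop$target, depth)
    pe <- percentage_error(max_normalize(target_scaled),
                           max_normalize(loop$measured))
    list(average_error_percent = pe$average_error_percent,
         error_trace = pe$error_trace,
         n_samples = length(pe$error_trace$values))
  })
}
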