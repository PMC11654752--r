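#' Per-wavelength LCD channel configuration
#'
#' Parameterizes the voltage-to-transmittance transfer of one wavelength
#' channel of the LCD-modulated phantom. Within the functional band
#' `[v_lo, v_hi]` transmittance falls smoothly from the open-state value
#' `t_open` down to `t_open * (1 - depth_max)`; outside the band the curve
#' continues with slope `tail_slope` (slightly positive by default), so a
#' full 0.5-3 V sweep is non-monotone, as real LCD responses are.
#'
#' A measured transfer curve may be supplied instead of the parametric shape
#' via `curve_table` (columns `voltage_v`, `transmittance`); it is then
#' linearly interpolated and the parametric fields are ignored.
#'
#' @param wavelength_nm Channel wavelength in nm.
#' @param depth_max Maximal modulation depth fraction in `(0, 1)`: the
#'   relative intensity drop across the functional band.
#' @param v_lo,v_hi Functional-band voltage bounds in volts (`v_lo < v_hi`).
#' @param t_open Open-state transmittance fraction in `(0, 1]`.
#' @param tail_slope Transmittance slope outside the band, fraction per volt.
#' @param curve_table Optional data frame `voltage_v,transmittance` replacing
#'   the parametric shape.
#' @return An object of class `channel_config`.
#' @export
channel_config <- function(wavelength_nm, depth_max, v_lo = 1.2, v_hi = 2.4,
                           t_open = 0.9, tail_slope = 0.02, curve_table = NULL) {
  stop_if_not_scalar(depth_max, "depth_max")
  if (depth_max <= 0 || depth_max >= 1) stop("`depth_max` must lie in (0, 1)", call. = FALSE)
  if (v_lo >= v_hi) stop("`v_lo` must be < `v_hi`", call. = FALSE)
  if (t_open <= 0 || t_open > 1) stop("`t_open` must lie in (0, 1]", call. = FALSE)
  if (!is.null(curve_table)) {
    if (!all(c("voltage_v", "transmittance") %in% names(curve_table))) {
      stop("`curve_table` needs columns `voltage_v` and `transmittance`", call. = FALSE)
    }
    if (any(diff(curve_table$voltage_v) <= 0)) {
      stop("`curve_table$voltage_v` must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(wavelength_nm = wavelength_nm, depth_max = depth_max,
         v_lo = v_lo, v_hi = v_hi, t_open = t_open, tail_slope = tail_slope,
         curve_table = curve_table),
    class = "channel_config"
  )
}

#' Phantom configuration: channels plus global settings
#'
#' Bundles the per-wavelength LCD channels with source intensity, DAC
#' quantization step, detector noise level, and inert metadata describing the
#' static tissue-mimicking top layer (target absorption 0.1 cm^-1, reduced
#' scattering 10 cm^-1, 0.5 mm thickness). The metadata is descriptive only:
#' light propagation through the silicone layer is abstracted into the
#' channel transfer curves and is not modeled.
#'
#' @param channels List of [channel_config()] objects (named by wavelength or
#'   not; they are re-keyed by wavelength).
#' @param source_intensity Source intensity in arbitrary units; a scalar
#'   shared by all channels or a vector named by wavelength.
#' @param dac_step_v DAC quantization step in volts (>= 0; 0 disables
#'   quantization).
#' @param detector_noise_sd Detector noise standard deviation as a fraction
#'   of source intensity (>= 0).
#' @param metadata List of inert descriptive fields.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(channels, source_intensity = 1,
                           dac_step_v = 1.526e-4, detector_noise_sd = 0,
                           metadata = list(mu_a_cm1 = 0.1, mu_s_prime_cm1 = 10,
                                           thickness_mm = 0.5)) {
  if (dac_step_v < 0) stop("`dac_step_v` must be >= 0", call. = FALSE)
  if (detector_noise_sd < 0) stop("`detector_noise_sd` must be >= 0", call. = FALSE)
  if (!length(channels)) stop("need at least one channel", call. = FALSE)
  ok <- vapply(channels, inherits, logical(1), what = "channel_config")
  if (!all(ok)) stop("`channels` must all be channel_config objects", call. = FALSE)
  names(channels) <- vapply(channels, function(ch) as.character(ch$wavelength_nm),
                            character(1))
  structure(
    list(channels = channels, source_intensity = source_intensity,
         dac_step_v = dac_step_v, detector_noise_sd = detector_noise_sd,
         metadata = metadata),
    class = "phantom_config"
  )
}

#' Default four-channel phantom fixture
#'
#' The configuration the studies and examples run against: channels at 940,
#' 660, 530, and 455 nm with maximal modulation depths 7%, 13%, 8%, and 2%
#' respectively, a shared functional band of 1.2-2.4 V, open-state
#' transmittance 0.9, a 16-bit-class DAC step of 1.526e-4 V, and noiseless
#' detection (noise is switched on per study).
#'
#' @return A [phantom_config()] with four channels.
#' @examples
#' ph <- default_phantom()
#' names(ph$channels)
#' @export
default_phantom <- function() {
  depths <- c("940" = 0.07, "660" = 0.13, "530" = 0.08, "455" = 0.02)
  channels <- lapply(names(depths), function(wl) {
    channel_config(as.integer(wl), depth_max = depths[[wl]])
  })
  phantom_config(channels)
}

# Fetch a channel by wavelength, with a clear error for unknown channels.
get_channel <- function(phantom, channel_nm) {
  stopifnot(inherits(phantom, "phantom_config"))
  key <- as.character(channel_nm)
  ch <- phantom$channels[[key]]
  if (is.null(ch)) {
    stop(sprintf("unknown channel %s nm (have: %s)", key,
                 paste(names(phantom$channels), collapse = ", ")), call. = FALSE)
  }
  ch
}

# Source intensity for one channel (scalar or named-by-wavelength vector).
get_source_intensity <- function(phantom, channel) {
  src <- phantom$source_intensity
  if (length(src) == 1L && is.null(names(src))) return(as.numeric(src))
  key <- as.character(channel$wavelength_nm)
  if (!is.null(names(src)) && key %in% names(src)) return(as.numeric(src[[key]]))
  as.numeric(src[[1L]])
}

#' LCD voltage-to-transmittance response
#'
#' Evaluates the channel transfer curve. The parametric shape is a cosine
#' ramp inside the functional band,
#' `t_open * (1 - depth_max * (1 - cos(pi * (v - v_lo) / (v_hi - v_lo))) / 2)`,
#' which is smooth, strictly decreasing on the band, and hits `t_open` at
#' `v_lo` and `t_open * (1 - depth_max)` at `v_hi`. Outside the band the
#' curve continues linearly with slope `tail_slope`.
#'
#' @param voltage_v Voltage(s) in volts (>= 0).
#' @param channel A [channel_config()].
#' @return Transmittance fraction(s), clamped to `[0, 1]`.
#' @export
lcd_response <- function(voltage_v, channel) {
  stopifnot(inherits(channel, "channel_config"))
  if (any(voltage_v < 0)) stop("`voltage_v` must be >= 0", call. = FALSE)
  if (!is.null(channel$curve_table)) {
    return(stats::approx(channel$curve_table$voltage_v,
                         channel$curve_table$transmittance,
                         xout = voltage_v, rule = 2)$y)
  }
  v_lo <- channel$v_lo; v_hi <- channel$v_hi
  t_open <- channel$t_open; d <- channel$depth_max; s <- channel$tail_slope
  u <- (voltage_v - v_lo) / (v_hi - v_lo)
  t_in <- t_open * (1 - d * (1 - cos(pi * u)) / 2)
  out <- ifelse(voltage_v < v_lo, t_open - s * (v_lo - voltage_v),
                ifelse(voltage_v > v_hi, t_open * (1 - d) + s * (voltage_v - v_hi),
                       t_in))
  clamp(out, 0, 1)
}

#' Simulate detection of a modulation-voltage trace
#'
#' The virtual detection chain: source intensity through the LCD channel onto
#' the detector, with optional additive Gaussian detector noise expressed as
#' a fraction of source intensity. A pure pointwise map when noiseless.
#'
#' @param voltage_trace A [signal_trace()] of drive voltages (unit volts).
#' @param channel A [channel_config()].
#' @param phantom A [phantom_config()] supplying source intensity and noise.
#' @param seed Integer seed for the noise RNG, or `NULL` for the ambient RNG.
#' @return A [signal_trace()] of detected intensities (arbitrary units).
#' @export
measure_intensity <- function(voltage_trace, channel, phantom, seed = NULL) {
  stopifnot(inherits(voltage_trace, "signal_trace"),
            inherits(channel, "channel_config"),
            inherits(phantom, "phantom_config"))
  i0 <- get_source_intensity(phantom, channel)
  vals <- i0 * lcd_response(voltage_trace$values, channel)
  if (phantom$detector_noise_sd > 0) {
    vals <- vals + with_seed(seed, {
      stats::rnorm(length(vals), 0, phantom$detector_noise_sd * i0)
    })
  }
  trace_like(voltage_trace, vals, unit = "a.u.",
             label = sprintf("%d nm intensity", channel$wavelength_nm))
}

#' Write a phantom configuration to JSON
#' @param phantom A [phantom_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phantom_json <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_config"))
  obj <- list(
    channels = lapply(phantom$channels, function(ch) {
      ch[!vapply(ch, is.null, logical(1))]
    }),
    source_intensity = phantom$source_intensity,
    dac_step_v = phantom$dac_step_v,
    detector_noise_sd = phantom$detector_noise_sd,
    metadata = phantom$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a phantom configuration from JSON
#' @param path Path written by [write_phantom_json()].
#' @return A [phantom_config()].
#' @export
read_phantom_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- lapply(seq_along(obj$channels), function(i) {
    ch <- obj$channels[[i]]
    tab <- ch$curve_table
    if (!is.null(tab)) tab <- as.data.frame(tab)
    channel_config(ch$wavelength_nm, ch$depth_max, ch$v_lo, ch$v_hi,
                   ch$t_open, ch$tail_slope, curve_table = tab)
  })
  phantom_config(channels,
                 source_intensity = obj$source_intensity,
                 dac_step_v = obj$dac_step_v,
                 detector_noise_sd = obj$detector_noise_sd,
                 metadata = obj$metadata)
}
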