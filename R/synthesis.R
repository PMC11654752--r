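#' Scale a normalized trace to a target modulation depth
#'
#' Affine map sending the trace maximum to 1 and the trace minimum to
#' `1 - depth`, so the output's `(max - min) / max` equals `depth` exactly.
#' The non-pulsatile (DC) component is anchored at the top of the band, which
#' lets one channel's amplitude be varied while another's is held constant
#' against a shared DC level.
#'
#' @param trace A [signal_trace()]; must be non-constant unless `depth = 0`.
#' @param depth Target modulation depth in `[0, 1)`.
#' @return A [signal_trace()] with values in `[1 - depth, 1]`, unit `"norm"`.
#' @export
scale_to_depth <- function(trace, depth) {
  stopifnot(inherits(trace, "signal_trace"))
  stop_if_not_scalar(depth, "depth")
  if (depth < 0 || depth >= 1) stop("`depth` must lie in [0, 1)", call. = FALSE)
  if (depth == 0) {
    return(trace_like(trace, rep(1, length(trace$values)), unit = "norm"))
  }
  hi <- max(trace$values); lo <- min(trace$values)
  if (hi <= lo) {
    stop("cannot scale a constant trace to a positive depth", call. = FALSE)
  }
  vals <- 1 - depth * (hi - trace$values) / (hi - lo)
  trace_like(trace, vals, unit = "norm")
}

#' Map a normalized target signal to a modulation-voltage trace
#'
#' Applies [lut_invert()] sample-wise: each normalized intensity target
#' becomes the drive voltage that reproduces it through the characterized
#' channel. Values outside `[1 - depth, 1]` are clamped (with a warning) by
#' the inversion. Output sampling rate equals the input's.
#'
#' @param lut A [build_lut()] result.
#' @param rel_intensity_trace A [signal_trace()] of normalized intensity
#'   targets, intended within `[1 - depth, 1]`.
#' @return A [signal_trace()] of voltages (unit `"V"`) carrying a
#'   `provenance` attribute naming the lookup table and target trace.
#' @export
map_signal <- function(lut, rel_intensity_trace) {
  stopifnot(inherits(lut, "lookup_table"),
            inherits(rel_intensity_trace, "signal_trace"))
  volts <- lut_invert(lut, rel_intensity_trace$values)
  out <- trace_like(rel_intensity_trace, volts, unit = "V",
                    label = sprintf("drive %s nm", lut$channel))
  attr(out, "provenance") <- list(
    lut_channel = lut$channel, v_lo = lut$v_lo, v_hi = lut$v_hi,
    lut_depth = lut$depth, target_label = rel_intensity_trace$label
  )
  out
}

#' Quantize a voltage trace to the DAC step
#'
#' Rounds every sample to the nearest multiple of `step_v`, bounding the
#' absolute error by `step_v / 2`. A step of 0 is the identity. Idempotent.
#'
#' @param trace A [signal_trace()] of voltages.
#' @param step_v DAC step in volts (>= 0).
#' @return A [signal_trace()] on the DAC grid; attributes preserved.
#' @export
quantize_dac <- function(trace, step_v) {
  stopifnot(inherits(trace, "signal_trace"))
  stop_if_not_scalar(step_v, "step_v")
  if (step_v < 0) stop("`step_v` must be >= 0", call. = FALSE)
  if (step_v == 0) return(trace)
  out <- trace_like(trace, round(trace$values / step_v) * step_v)
  attr(out, "provenance") <- attr(trace, "provenance")
  out
}

#' Full synthesis chain for one channel
#'
#' Target normalized PPG to DAC-quantized modulation voltages: depth scaling,
#' lookup-table inversion, quantization. The requested depth must not exceed
#' the lookup table's depth; each channel has a hard modulation ceiling and
#' exceeding it cannot be honored, so it raises an error rather than
#' silently flattening the waveform.
#'
#' @param lut A [build_lut()] result.
#' @param target_trace A max-normalized [signal_trace()].
#' @param depth Modulation depth to impose (default 0.01, a typical resting
#'   perfusion index).
#' @param dac_step_v DAC step in volts.
#' @return A quantized modulation-voltage [signal_trace()].
#' @export
synthesize_modulation <- function(lut, target_trace, depth = 0.01,
                                  dac_step_v = 1.526e-4) {
  stopifnot(inherits(lut, "lookup_table"))
  if (depth > lut$depth) {
    stop(sprintf("requested depth %.4g exceeds channel depth ceiling %.4g",
                 depth, lut$depth), call. = FALSE)
  }
  scaled <- scale_to_depth(target_trace, depth)
  quantize_dac(map_signal(lut, scaled), dac_step_v)
}
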