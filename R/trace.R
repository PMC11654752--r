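#' Uniformly sampled signal trace
#'
#' The basic container the whole pipeline works with: a uniformly sampled
#' time series of light intensity, normalized signal, or drive voltage.
#' Sample times are implied by index: `time[i] = start_time_s + (i - 1) /
#' sampling_rate_hz`, so the duration is `n_samples / sampling_rate_hz`.
#'
#' @param values Numeric vector of samples (non-empty, finite).
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param start_time_s Time of the first sample in seconds.
#' @param unit Free-text unit tag, e.g. `"a.u."`, `"norm"`, `"V"`.
#' @param label Free-text label, e.g. the wavelength channel.
#'
#' @return An object of class `signal_trace`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * seq(0, 1, by = 0.01)), 100)
#' duration(tr)
#' @export
signal_trace <- function(values, sampling_rate_hz, start_time_s = 0,
                         unit = "a.u.", label = "") {
  stop_if_not_scalar(sampling_rate_hz, "sampling_rate_hz")
  stop_if_not_scalar(start_time_s, "start_time_s")
  if (sampling_rate_hz <= 0) stop("`sampling_rate_hz` must be > 0", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  structure(
    list(
      values = values,
      sampling_rate_hz = sampling_rate_hz,
      start_time_s = start_time_s,
      unit = unit,
      label = label
    ),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf(
    "<signal_trace> %d samples @ %g Hz (%.4g s)%s%s\n",
    length(x$values), x$sampling_rate_hz, duration(x),
    if (nzchar(x$unit)) paste0(", unit: ", x$unit) else "",
    if (nzchar(x$label)) paste0(", label: ", x$label) else ""
  ))
  cat(sprintf("  range [%.6g, %.6g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace A [signal_trace()].
#' @return `n_samples / sampling_rate_hz`, in seconds.
#' @export
duration <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  length(trace$values) / trace$sampling_rate_hz
}

#' Sample times of a trace
#' @param trace A [signal_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  trace$start_time_s + (seq_along(trace$values) - 1) / trace$sampling_rate_hz
}

#' @export
as.data.frame.signal_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), value = x$values)
}

# Build a modified copy of a trace keeping rate/start/label unless overridden.
trace_like <- function(trace, values, unit = trace$unit, label = trace$label,
                       sampling_rate_hz = trace$sampling_rate_hz,
                       start_time_s = trace$start_time_s) {
  signal_trace(values, sampling_rate_hz, start_time_s, unit = unit, label = label)
}

#' Read a signal trace from CSV
#'
#' Expects a header `time_s,value` with one row per sample and a strictly
#' uniform time step; the step is validated to within 1e-6 s so that an
#' irregularly sampled file is rejected rather than silently resampled.
#'
#' @param path Path to a CSV file.
#' @param unit,label Unit and label to attach to the trace.
#' @return A [signal_trace()].
#' @export
read_signal_csv <- function(path, unit = "a.u.", label = "") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("CSV must have columns `time_s` and `value`", call. = FALSE)
  }
  if (nrow(df) < 2L) stop("need at least 2 samples to infer a sampling rate", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("`time_s` must be strictly increasing", call. = FALSE)
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 1e-6) {
    stop("`time_s` is not uniformly sampled (tolerance 1e-6 s)", call. = FALSE)
  }
  signal_trace(df$value, sampling_rate_hz = 1 / step,
               start_time_s = df$time_s[1L], unit = unit, label = label)
}

#' Write a signal trace to CSV
#'
#' Writes the `time_s,value` format read back by [read_signal_csv()].
#'
#' @param trace A [signal_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
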