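#' Parametric beat morphology for synthetic PPG
#'
#' A PPG pulse is modeled as two positive Gaussian bumps on a baseline: the
#' systolic peak and the (smaller, later) diastolic peak. The dicrotic notch
#' arises naturally in the valley between the two bumps; an optional explicit
#' notch dip can deepen it. Centers and widths are expressed as fractions of
#' the beat period so the same morphology serves any heart rate.
#'
#' @param systolic_amplitude Height of the systolic bump (dimensionless, >= 0).
#' @param systolic_center Center of the systolic bump, fraction of the beat
#'   period in `[0, 1)`.
#' @param systolic_width Gaussian width (s.d.) of the systolic bump, fraction
#'   of the beat period (> 0).
#' @param diastolic_amplitude Height of the diastolic bump; must be smaller
#'   than the systolic amplitude.
#' @param diastolic_center,diastolic_width Center and width of the diastolic
#'   bump, as above.
#' @param notch_depth Depth of an optional explicit dicrotic-notch dip
#'   (dimensionless, >= 0; default 0 leaves the natural inter-bump valley).
#' @param notch_center,notch_width Center and width of the notch dip; default
#'   midway between the two bumps, narrow.
#' @param baseline Constant baseline level added to every sample.
#'
#' @return An object of class `beat_morphology`.
#' @export
beat_morphology <- function(systolic_amplitude = 1, systolic_center = 0.22,
                            systolic_width = 0.07,
                            diastolic_amplitude = 0.35, diastolic_center = 0.55,
                            diastolic_width = 0.12,
                            notch_depth = 0, notch_center = NULL,
                            notch_width = 0.03,
                            baseline = 0) {
  if (is.null(notch_center)) notch_center <- (systolic_center + diastolic_center) / 2
  m <- list(
    systolic_amplitude = systolic_amplitude, systolic_center = systolic_center,
    systolic_width = systolic_width,
    diastolic_amplitude = diastolic_amplitude, diastolic_center = diastolic_center,
    diastolic_width = diastolic_width,
    notch_depth = notch_depth, notch_center = notch_center,
    notch_width = notch_width, baseline = baseline
  )
  if (m$systolic_amplitude < 0 || m$diastolic_amplitude < 0 || m$notch_depth < 0) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (m$diastolic_amplitude >= m$systolic_amplitude) {
    stop("`diastolic_amplitude` must be smaller than `systolic_amplitude`", call. = FALSE)
  }
  centers <- c(m$systolic_center, m$diastolic_center, m$notch_center)
  if (any(centers < 0 | centers >= 1)) stop("centers must lie in [0, 1)", call. = FALSE)
  if (m$systolic_width <= 0 || m$diastolic_width <= 0 || m$notch_width <= 0) {
    stop("widths must be > 0", call. = FALSE)
  }
  structure(m, class = "beat_morphology")
}

# Periodic Gaussian bump in beat phase; wraps across the beat boundary.
periodic_bump <- function(phase, center, width, amplitude) {
  out <- 0
  for (k in -1:1) {
    out <- out + amplitude * exp(-0.5 * ((phase - center - k) / width)^2)
  }
  out
}

# Waveform value at a vector of beat phases in [0, 1).
beat_shape <- function(phase, morphology) {
  m <- morphology
  m$baseline +
    periodic_bump(phase, m$systolic_center, m$systolic_width, m$systolic_amplitude) +
    periodic_bump(phase, m$diastolic_center, m$diastolic_width, m$diastolic_amplitude) -
    periodic_bump(phase, m$notch_center, m$notch_width, m$notch_depth)
}

#' Synthesize a PPG-like signal trace
#'
#' Generates a pulsatile waveform by evaluating a parametric two-bump beat
#' morphology at the instantaneous beat phase. With `hr_jitter_frac = 0` the
#' signal is exactly periodic with period `60 / heart_rate_bpm` seconds; with
#' jitter, each beat period is independently perturbed by a Gaussian factor.
#'
#' @param heart_rate_bpm Heart rate in beats per minute, in `[30, 240]`.
#' @param duration_s Record duration in seconds (> 0).
#' @param sampling_rate_hz Sampling rate in Hz; must be at least four times
#'   the beat frequency.
#' @param morphology A [beat_morphology()].
#' @param hr_jitter_frac Standard deviation of per-beat period perturbation,
#'   as a fraction of the period (>= 0; default 0).
#' @param seed Integer seed for the jitter RNG, or `NULL` to use the ambient
#'   RNG state.
#'
#' @return A [signal_trace()] of `round(duration_s * sampling_rate_hz)`
#'   samples, unit `"norm"`.
#' @examples
#' tr <- synth_ppg(80, 20, 1000)
#' length(tr$values) # 20000
#' @export
synth_ppg <- function(heart_rate_bpm, duration_s, sampling_rate_hz,
                      morphology = beat_morphology(), hr_jitter_frac = 0,
                      seed = NULL) {
  stop_if_not_scalar(heart_rate_bpm, "heart_rate_bpm")
  stop_if_not_scalar(duration_s, "duration_s")
  stop_if_not_scalar(sampling_rate_hz, "sampling_rate_hz")
  if (heart_rate_bpm < 30 || heart_rate_bpm > 240) {
    stop("`heart_rate_bpm` must lie in [30, 240]", call. = FALSE)
  }
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  if (sampling_rate_hz < 4 * heart_rate_bpm / 60) {
    stop("sampling rate below pulse bandwidth (need >= 4 beats-per-second)", call. = FALSE)
  }
  if (hr_jitter_frac < 0) stop("`hr_jitter_frac` must be >= 0", call. = FALSE)
  stopifnot(inherits(morphology, "beat_morphology"))

  n <- round(duration_s * sampling_rate_hz)
  times <- (seq_len(n) - 1) / sampling_rate_hz
  period <- 60 / heart_rate_bpm

  if (hr_jitter_frac == 0) {
    phase <- (times / period) %% 1
  } else {
    phase <- with_seed(seed, {
      n_beats <- ceiling(duration_s / period) + 2L
      periods <- period * pmax(0.2, 1 + stats::rnorm(n_beats, 0, hr_jitter_frac))
      onsets <- c(0, cumsum(periods))
      beat <- findInterval(times, onsets)
      (times - onsets[beat]) / periods[beat]
    })
  }
  values <- beat_shape(phase, morphology)
  signal_trace(values, sampling_rate_hz, unit = "norm",
               label = sprintf("ppg_%gbpm", heart_rate_bpm))
}

#' Normalize a trace to its maximum
#'
#' Divides every sample by the global maximum of the record so the output
#' maximum is exactly 1. Whole records are normalized (not per beat), matching
#' how the lookup-table pipeline normalizes its target signals.
#'
#' @param trace A [signal_trace()] with a strictly positive maximum.
#' @return A [signal_trace()] with `max(values) == 1`, unit `"norm"`.
#' @export
max_normalize <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  m <- max(trace$values)
  if (m <= 0) stop("trace maximum must be > 0 to max-normalize", call. = FALSE)
  trace_like(trace, trace$values / m, unit = "norm")
}

#' Resample a trace to a new rate
#'
#' Linear interpolation at the new sample times; adequate for smooth PPG
#' content well below the new Nyquist frequency. No anti-alias filter is
#' applied, which is a documented limitation for aggressive downsampling of
#' broadband content.
#'
#' @param trace A [signal_trace()].
#' @param new_rate_hz Target sampling rate in Hz (> 0).
#' @return A [signal_trace()] at `new_rate_hz` covering the same duration to
#'   within one sample period.
#' @export
resample_trace <- function(trace, new_rate_hz) {
  stopifnot(inherits(trace, "signal_trace"))
  stop_if_not_scalar(new_rate_hz, "new_rate_hz")
  if (new_rate_hz <= 0) stop("`new_rate_hz` must be > 0", call. = FALSE)
  if (new_rate_hz == trace$sampling_rate_hz) return(trace)
  n_new <- max(1L, round(duration(trace) * new_rate_hz))
  new_times <- trace$start_time_s + (seq_len(n_new) - 1) / new_rate_hz
  vals <- stats::approx(trace_times(trace), trace$values, xout = new_times,
                        rule = 2)$y
  trace_like(trace, vals, sampling_rate_hz = new_rate_hz)
}

#' Add noise or artifacts to a trace
#'
#' Injects one of three disturbance types used to emulate detector noise and
#' motion artifacts: `"white"` adds zero-mean Gaussian noise with standard
#' deviation `magnitude` (in trace units); `"drift"` adds a low-frequency
#' (< 0.5 Hz) sinusoid of amplitude `magnitude` with randomized frequency and
#' phase; `"spikes"` adds sparse impulses of height `magnitude` at
#' Poisson-distributed times.
#'
#' @param trace A [signal_trace()].
#' @param noise_kind One of `"white"`, `"drift"`, `"spikes"`.
#' @param magnitude Disturbance magnitude in trace units (>= 0); 0 returns the
#'   input unchanged.
#' @param seed Integer seed, or `NULL` for the ambient RNG.
#' @param spike_rate_hz Mean impulse rate for `"spikes"` (events per second).
#' @return A [signal_trace()] with the disturbance added.
#' @export
add_noise <- function(trace, noise_kind = c("white", "drift", "spikes"),
                      magnitude, seed = NULL, spike_rate_hz = 0.2) {
  stopifnot(inherits(trace, "signal_trace"))
  noise_kind <- match.arg(noise_kind)
  stop_if_not_scalar(magnitude, "magnitude")
  if (magnitude < 0) stop("`magnitude` must be >= 0", call. = FALSE)
  if (magnitude == 0) return(trace)
  n <- length(trace$values)
  times <- trace_times(trace)
  noise <- with_seed(seed, {
    switch(noise_kind,
      white = stats::rnorm(n, 0, magnitude),
      drift = {
        freq <- stats::runif(1, 0.05, 0.45)
        phi <- stats::runif(1, 0, 2 * pi)
        magnitude * sin(2 * pi * freq * times + phi)
      },
      spikes = {
        k <- stats::rpois(1, spike_rate_hz * duration(trace))
        out <- numeric(n)
        if (k > 0) {
          idx <- unique(pmin(n, pmax(1L, round(stats::runif(k, 0, duration(trace)) *
                                                 trace$sampling_rate_hz) + 1L)))
          out[idx] <- magnitude
        }
        out
      }
    )
  })
  trace_like(trace, trace$values + noise)
}
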