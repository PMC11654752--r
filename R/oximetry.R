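# Empirical linear pulse-oximeter calibration, valid for SpO2 in [86, 100]%:
# SpO2 = -24.87 R + 113.8.
SPO2_SLOPE <- -24.87
SPO2_INTERCEPT <- 113.8
SPO2_CAL_RANGE <- c(86, 100)

#' SpO2 from the R ratio
#'
#' Applies the empirical linear calibration `SpO2 = -24.87 R + 113.8`,
#' stated for the 86-100% saturation range. The output is not clipped;
#' callers may clip for display.
#'
#' @param r R ratio(s), >= 0.
#' @return SpO2 in percent.
#' @export
spo2_from_r <- function(r) {
  if (any(r < 0)) stop("`r` must be >= 0", call. = FALSE)
  SPO2_SLOPE * r + SPO2_INTERCEPT
}

#' R ratio from SpO2
#'
#' Exact linear inverse of [spo2_from_r()]: `R = (113.8 - SpO2) / 24.87`.
#'
#' @param spo2_percent SpO2 in percent, <= 113.8.
#' @return R ratio(s).
#' @export
r_from_spo2 <- function(spo2_percent) {
  if (any(spo2_percent > SPO2_INTERCEPT)) {
    stop(sprintf("`spo2_percent` must be <= %.1f", SPO2_INTERCEPT), call. = FALSE)
  }
  (SPO2_INTERCEPT - spo2_percent) / (-SPO2_SLOPE)
}

#' 660 nm modulation depth for a target SpO2
#'
#' Design calculation for the oxygen-saturation study: holding the 940 nm
#' modulation depth fixed, find the 660 nm depth whose per-pulse R ratio
#' equals the calibration value for the requested saturation. From the
#' definition of R with `Imax = 1`, `Imin = 1 - d` on both channels,
#' `R = ln(1 - d660) / ln(1 - d940)`, giving the closed form
#' `d660 = 1 - (1 - d940)^R` with `R = r_from_spo2(spo2)`.
#'
#' @param spo2_percent Target saturation in percent; the calibration is
#'   stated for `[86, 100]` and values outside it draw a warning.
#' @param depth_940 Fixed 940 nm modulation depth in `(0, 1)`.
#' @return The 660 nm modulation depth.
#' @export
depth_for_spo2 <- function(spo2_percent, depth_940) {
  stop_if_not_scalar(spo2_percent, "spo2_percent")
  stop_if_not_scalar(depth_940, "depth_940")
  if (depth_940 <= 0 || depth_940 >= 1) {
    stop("`depth_940` must lie in (0, 1)", call. = FALSE)
  }
  if (spo2_percent < SPO2_CAL_RANGE[1] || spo2_percent > SPO2_CAL_RANGE[2]) {
    warning(sprintf("SpO2 %.4g%% is outside the linear calibration range [%g, %g]%%",
                    spo2_percent, SPO2_CAL_RANGE[1], SPO2_CAL_RANGE[2]),
            call. = FALSE)
  }
  r <- r_from_spo2(spo2_percent)
  d660 <- 1 - (1 - depth_940)^r
  if (d660 >= 1) stop("resulting 660 nm depth >= 1: unreachable", call. = FALSE)
  if (d660 <= 0) stop("resulting 660 nm depth <= 0: unreachable", call. = FALSE)
  d660
}

#' Per-pulse R ratio of two paired pulses
#'
#' The "ratio of ratios" of pulsatile to non-pulsatile components:
#' `R = ln(Imax_660 / Imin_660) / ln(Imax_940 / Imin_940)`, computed per
#' pulse. Scale-invariant in each channel's intensities.
#'
#' @param p660,p940 `pulse_feature` rows (see [segment_pulses()]) for the red
#'   and near-infrared channels.
#' @return The dimensionless R ratio.
#' @export
pulse_r <- function(p660, p940) {
  for (p in list(p660, p940)) {
    if (!(p$i_max > p$i_min && p$i_min > 0)) {
      stop("pulse features require i_max > i_min > 0", call. = FALSE)
    }
  }
  denom <- log(p940$i_max / p940$i_min)
  if (denom == 0) stop("zero 940 nm pulsatility: R undefined", call. = FALSE)
  log(p660$i_max / p660$i_min) / denom
}

# Greedy extremum selection: candidates ordered by preference (best first)
# are accepted if at least `min_gap` samples from every accepted index.
select_separated <- function(candidates, order_by, min_gap) {
  ord <- candidates[order(order_by)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_gap)) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted)
}

#' Segment a pulsatile trace into complete pulses
#'
#' Delimits pulses trough-to-trough. Detection runs peaks-first, the standard
#' approach for PPG: systolic peaks are amplitude-gated local maxima (upper
#' 40% of the smoothed signal range) separated by at least `60 / hr_max_bpm`
#' seconds; each trough is then the interior minimum between two consecutive
#' peaks. Edge segments before the first and after the last peak contribute a
#' trough only if their minimum lies clear of the record boundary, so partial
#' leading/trailing pulses are discarded. Detection operates on a lightly
#' smoothed copy of the trace (centered moving average, `smooth_window_s`
#' wide) to keep trough timing stable under detector noise; trough times are
#' refined by a basin centroid below a low threshold, which localizes the
#' flat diastolic foot far better than a raw argmin.
#'
#' Each pulse reports `i_max` (systolic maximum within the segment) and
#' `i_min`/`t_min` taken at the pulse onset (leading trough), the usual
#' convention for per-beat AC/DC extraction.
#'
#' @param trace A [signal_trace()] of positive samples.
#' @param hr_min_bpm,hr_max_bpm Plausible heart-rate band; `hr_max_bpm` sets
#'   the minimum peak separation and `hr_min_bpm` the minimum record length.
#' @param smooth_window_s Width of the detection smoothing window in seconds
#'   (0 disables smoothing).
#' @param refine_troughs Refine trough times by basin centroid (default TRUE).
#' @return A data frame of class `pulse_feature` with columns `pulse_index`,
#'   `i_max`, `i_min`, `t_max`, `t_min`, and an attribute `trough_times_s`
#'   holding the full strictly increasing trough sequence (one more entry
#'   than pulses).
#' @export
segment_pulses <- function(trace, hr_min_bpm = 40, hr_max_bpm = 220,
                           smooth_window_s = 0.08, refine_troughs = TRUE) {
  stopifnot(inherits(trace, "signal_trace"))
  if (hr_min_bpm <= 0 || hr_max_bpm <= hr_min_bpm) {
    stop("need 0 < hr_min_bpm < hr_max_bpm", call. = FALSE)
  }
  if (any(trace$values <= 0)) {
    stop("`trace` must have positive samples", call. = FALSE)
  }
  if (duration(trace) < 60 / hr_min_bpm) {
    stop("trace shorter than one period at `hr_min_bpm`", call. = FALSE)
  }
  fs <- trace$sampling_rate_hz
  x <- moving_average(trace$values, round(smooth_window_s * fs))
  n <- length(x)
  times <- trace_times(trace)
  rng <- max(x) - min(x)
  if (rng <= 0) stop("no pulses detectable: trace is constant", call. = FALSE)

  min_gap <- max(1, 60 / hr_max_bpm * fs)

  # systolic peaks: amplitude-gated local maxima, tallest kept first
  interior <- 2:(n - 1)
  is_max <- x[interior] > x[interior - 1L] & x[interior] >= x[interior + 1L]
  peak_cand <- interior[is_max & x[interior] >= min(x) + 0.6 * rng]
  peaks <- select_separated(peak_cand, -x[peak_cand], min_gap)
  if (length(peaks) < 2L) {
    stop("fewer than one complete pulse in the trace", call. = FALSE)
  }

  # troughs: interior minima between consecutive peaks, plus edge segments
  # whose minimum sits clear (>= 2 samples) of the record boundary
  seg_bounds <- cbind(peaks[-length(peaks)], peaks[-1L])
  troughs <- apply(seg_bounds, 1L, function(b) {
    seg <- b[1L]:b[2L]
    seg[which.min(x[seg])]
  })
  # Edge segments (before the first / after the last peak) may contain only a
  # partial pulse whose lowest point is the dicrotic notch, not a trough;
  # accept an edge minimum only if it sits clear of the record boundary and
  # at the amplitude level of the interior troughs.
  trough_gate <- if (length(troughs)) {
    # median, not max: a noisy outlier trough must not widen the gate enough
    # to admit a dicrotic notch sitting in a partial edge segment
    stats::median(x[troughs]) +
      0.1 * (stats::median(x[peaks]) - stats::median(x[troughs]))
  } else {
    min(x) + 0.25 * rng
  }
  lead_seg <- 1:peaks[1L]
  i <- lead_seg[which.min(x[lead_seg])]
  if (i >= 3L && i <= peaks[1L] - 1L && x[i] <= trough_gate) {
    troughs <- c(i, troughs)
  }
  tail_seg <- peaks[length(peaks)]:n
  i <- tail_seg[which.min(x[tail_seg])]
  if (i <= n - 2L && i >= peaks[length(peaks)] + 1L && x[i] <= trough_gate) {
    troughs <- c(troughs, i)
  }
  troughs <- sort(unique(troughs))
  if (length(troughs) < 2L) {
    stop("fewer than one complete pulse in the trace", call. = FALSE)
  }

  trough_times <- times[troughs]
  if (refine_troughs) {
    trough_times <- vapply(seq_along(troughs), function(k) {
      i_tr <- troughs[k]
      lo <- if (k == 1L) max(1L, peaks[1L] - as.integer(min_gap)) else troughs[k - 1L]
      hi <- if (k == length(troughs)) n else troughs[k + 1L]
      # restrict to the basin: samples below a low threshold around the trough
      win <- lo:hi
      thr <- x[i_tr] + 0.2 * (max(x[win]) - x[i_tr])
      w <- pmax(0, thr - x[win])
      if (sum(w) <= 0) return(times[i_tr])
      # keep only the contiguous basin containing the trough
      inb <- w > 0
      runs <- rle(inb)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      k_run <- which(starts <= (i_tr - lo + 1L) & ends >= (i_tr - lo + 1L) & runs$values)
      if (length(k_run)) {
        sel <- starts[k_run[1L]]:ends[k_run[1L]]
        sum(w[sel] * times[win[sel]]) / sum(w[sel])
      } else {
        times[i_tr]
      }
    }, numeric(1))
  }

  n_pulses <- length(troughs) - 1L
  feats <- data.frame(
    pulse_index = seq_len(n_pulses),
    i_max = NA_real_, i_min = NA_real_, t_max = NA_real_, t_min = NA_real_
  )
  for (k in seq_len(n_pulses)) {
    seg <- troughs[k]:troughs[k + 1L]
    im <- seg[which.max(x[seg])]
    feats$i_max[k] <- x[im]
    feats$t_max[k] <- times[im]
    feats$i_min[k] <- x[troughs[k]] # pulse onset (leading trough)
    feats$t_min[k] <- trough_times[k]
  }
  class(feats) <- c("pulse_feature", "data.frame")
  attr(feats, "trough_times_s") <- trough_times
  feats
}

#' Estimate SpO2 from paired red/near-infrared traces
#'
#' Segments both channels into pulses, pairs pulses by index, computes the
#' per-pulse R ratio, averages R arithmetically over the analysis window, and
#' maps the mean through the linear calibration. A one-pulse count mismatch
#' drops the unpaired terminal pulse; larger mismatches are an error, as is a
#' sampling-rate or duration mismatch.
#'
#' @param trace660,trace940 [signal_trace()]s of the red and near-infrared
#'   channels, same sampling rate and duration.
#' @param window_s Averaging window in seconds (pulses whose onset falls
#'   inside the window are used; default 6).
#' @param hr_band Plausible heart-rate band `c(min, max)` in bpm for
#'   segmentation.
#' @param ... Further arguments passed to [segment_pulses()].
#' @return An object of class `oximetry_estimate`: `per_pulse_r`, `r_mean`,
#'   `spo2`, `window_s`, `n_pulses`, and the calibration validity range.
#' @export
estimate_spo2 <- function(trace660, trace940, window_s = 6,
                          hr_band = c(40, 220), ...) {
  stopifnot(inherits(trace660, "signal_trace"), inherits(trace940, "signal_trace"))
  if (trace660$sampling_rate_hz != trace940$sampling_rate_hz) {
    stop("sampling rates of the two channels must match", call. = FALSE)
  }
  if (abs(duration(trace660) - duration(trace940)) > 1 / trace660$sampling_rate_hz) {
    stop("durations of the two channels must match", call. = FALSE)
  }
  p660 <- segment_pulses(trace660, hr_band[1], hr_band[2], ...)
  p940 <- segment_pulses(trace940, hr_band[1], hr_band[2], ...)
  n660 <- nrow(p660); n940 <- nrow(p940)
  if (abs(n660 - n940) > 1L) {
    stop(sprintf("pulse-count mismatch beyond 1 (%d vs %d)", n660, n940),
         call. = FALSE)
  }
  n_pair <- min(n660, n940)
  keep <- seq_len(n_pair)
  t0 <- min(p660$t_min[1L], p940$t_min[1L])
  in_window <- p660$t_min[keep] - t0 < window_s
  keep <- keep[in_window]
  if (!length(keep)) stop("no pulses inside the averaging window", call. = FALSE)
  r <- vapply(keep, function(k) pulse_r(p660[k, ], p940[k, ]), numeric(1))
  structure(
    list(per_pulse_r = r, r_mean = mean(r), spo2 = spo2_from_r(mean(r)),
         window_s = window_s, n_pulses = length(r),
         calibration_range_percent = SPO2_CAL_RANGE),
    class = "oximetry_estimate"
  )
}

#' @export
print.oximetry_estimate <- function(x, ...) {
  cat(sprintf("<oximetry_estimate> %d pulses over %g s: mean R = %.4f, SpO2 = %.2f%%\n",
              x$n_pulses, x$window_s, x$r_mean, x$spo2))
  cat(sprintf("  (linear calibration valid for %g-%g%%)\n",
              x$calibration_range_percent[1], x$calibration_range_percent[2]))
  invisible(x)
}
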