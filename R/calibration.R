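#' Raw voltage-sweep transfer curve
#'
#' Holds a measured (or simulated) intensity-versus-voltage sweep of one
#' channel, before functional-range restriction and normalization.
#'
#' @param voltages_v Strictly increasing voltages (V), length >= 3.
#' @param intensities Same-length intensities (arbitrary units).
#' @param channel Free-text channel label.
#' @return An object of class `transfer_curve`.
#' @export
transfer_curve <- function(voltages_v, intensities, channel = "") {
  voltages_v <- as.numeric(voltages_v)
  intensities <- as.numeric(intensities)
  if (length(voltages_v) != length(intensities)) {
    stop("`voltages_v` and `intensities` must have equal length", call. = FALSE)
  }
  if (length(voltages_v) < 3L) stop("need at least 3 sweep points", call. = FALSE)
  if (any(diff(voltages_v) <= 0)) {
    stop("`voltages_v` must be strictly increasing", call. = FALSE)
  }
  structure(list(voltages_v = voltages_v, intensities = intensities,
                 channel = channel),
            class = "transfer_curve")
}

#' Sweep a phantom channel over a voltage grid
#'
#' Characterizes one channel by stepping the drive voltage over an arithmetic
#' grid (default 0.5-3 V in 0.05 V steps, 51 points) and recording the
#' detected intensity at each point, averaged over `n_repeats` measurements.
#'
#' @param phantom A [phantom_config()].
#' @param channel_nm Wavelength of the channel to sweep.
#' @param v_start,v_stop,v_step Grid start, stop (inclusive; the last point is
#'   clipped to `v_stop`), and step, in volts.
#' @param n_repeats Number of measurements averaged per grid point.
#' @param seed Integer seed for detector noise, or `NULL`.
#' @return A [transfer_curve()].
#' @export
sweep_channel <- function(phantom, channel_nm, v_start = 0.5, v_stop = 3.0,
                          v_step = 0.05, n_repeats = 1, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_config"))
  if (v_start >= v_stop) stop("`v_start` must be < `v_stop`", call. = FALSE)
  if (v_step <= 0) stop("`v_step` must be > 0", call. = FALSE)
  if (n_repeats < 1) stop("`n_repeats` must be >= 1", call. = FALSE)
  channel <- get_channel(phantom, channel_nm)

  grid <- seq(v_start, v_stop + v_step * 1e-9, by = v_step)
  grid[length(grid)] <- min(grid[length(grid)], v_stop)
  if (v_stop - grid[length(grid)] > v_step * 1e-6) grid <- c(grid, v_stop)

  i0 <- get_source_intensity(phantom, channel)
  resp <- i0 * lcd_response(grid, channel)
  intensities <- with_seed(seed, {
    if (phantom$detector_noise_sd > 0) {
      noise <- matrix(stats::rnorm(length(grid) * n_repeats, 0,
                                   phantom$detector_noise_sd * i0),
                      nrow = length(grid))
      resp + rowMeans(noise)
    } else {
      resp
    }
  })
  transfer_curve(grid, intensities, channel = as.character(channel_nm))
}

#' Detect the functional voltage range of a sweep
#'
#' The functional range is the voltage interval over which intensity is
#' negatively correlated with voltage. Operationally: the longest contiguous
#' run of grid steps on which intensity falls by more than
#' `drop_tolerance * (max - min)` of the curve, with ties between equal-length
#' runs broken toward lower voltage. Endpoints snap to grid points.
#'
#' The result is invariant to uniform intensity scaling of the curve.
#'
#' @param curve A [transfer_curve()].
#' @param drop_tolerance Relative drop (fraction of the curve's global
#'   intensity range) a step must exceed to count as decreasing; absorbs
#'   detector noise.
#' @return Named numeric vector `c(v_lo = , v_hi = )`.
#' @export
find_functional_range <- function(curve, drop_tolerance = 0.002) {
  stopifnot(inherits(curve, "transfer_curve"))
  y <- curve$intensities
  rng <- max(y) - min(y)
  if (rng <= 0) stop("no functional range: curve is constant", call. = FALSE)
  thr <- drop_tolerance * rng
  dec <- diff(y) < -thr

  runs <- rle(dec)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= 2L # >= 2 decreasing steps = >= 3 points
  if (!any(keep)) {
    stop("no functional range: no decreasing run of >= 3 points", call. = FALSE)
  }
  best <- which(keep)[which.max(runs$lengths[keep])] # which.max: first = lowest V
  i_lo <- starts[best]
  i_hi <- ends[best] + 1L # run of steps [i, i+1] covers points i..i+1
  c(v_lo = curve$voltages_v[i_lo], v_hi = curve$voltages_v[i_hi])
}

#' Normalized monotone lookup table
#'
#' Restricts a transfer curve to the functional band, normalizes it to the
#' band maximum (first value exactly 1), and enforces a strictly decreasing
#' profile. Noisy curves are made monotone by isotonic (pool-adjacent-
#' violators) regression before a tie-breaking epsilon strictification;
#' inversion requires strict monotonicity.
#'
#' @param curve A [transfer_curve()].
#' @param v_lo,v_hi Band bounds (must contain >= 3 grid points of the curve).
#' @return An object of class `lookup_table` with fields `voltages_v`,
#'   `normalized_intensities`, `v_lo`, `v_hi`, `depth` (1 minus the last
#'   normalized value), and `channel`.
#' @export
build_lut <- function(curve, v_lo, v_hi) {
  stopifnot(inherits(curve, "transfer_curve"))
  if (v_lo >= v_hi) stop("`v_lo` must be < `v_hi`", call. = FALSE)
  eps_v <- 1e-9
  idx <- which(curve$voltages_v >= v_lo - eps_v & curve$voltages_v <= v_hi + eps_v)
  if (length(idx) < 3L) {
    stop("band too narrow: fewer than 3 grid points in [v_lo, v_hi]", call. = FALSE)
  }
  v <- curve$voltages_v[idx]
  y <- curve$intensities[idx]
  if (max(y) <= 0) stop("band maximum must be > 0", call. = FALSE)
  y <- y / max(y)

  # isotonic decreasing fit (PAVA on the negated values)
  y_mono <- -stats::isoreg(v, -y)$yf
  y_mono <- y_mono / y_mono[1L] # head exactly 1
  # strictify flat blocks left by PAVA with a descending epsilon ladder
  for (i in 2:length(y_mono)) {
    if (y_mono[i] >= y_mono[i - 1L]) y_mono[i] <- y_mono[i - 1L] - 1e-9
  }
  depth <- 1 - y_mono[length(y_mono)]
  if (depth <= 0 || depth >= 1) {
    stop("degenerate lookup table: depth must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(voltages_v = v, normalized_intensities = y_mono,
         v_lo = v[1L], v_hi = v[length(v)], depth = depth,
         channel = curve$channel),
    class = "lookup_table"
  )
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("<lookup_table> channel %s: %d points, band [%g, %g] V, depth %.4f\n",
              x$channel, length(x$voltages_v), x$v_lo, x$v_hi, x$depth))
  invisible(x)
}

#' Invert a lookup table: normalized intensity to drive voltage
#'
#' Piecewise-linear interpolation of voltage as a function of normalized
#' intensity. Targets above 1 clamp to `v_lo`, targets below `1 - depth`
#' clamp to `v_hi`; both clamps emit a warning. Monotone: larger targets map
#' to smaller (or equal) voltages.
#'
#' @param lut A [build_lut()] result.
#' @param target Normalized intensity target(s).
#' @return Voltage(s) in volts.
#' @export
lut_invert <- function(lut, target) {
  stopifnot(inherits(lut, "lookup_table"))
  y <- lut$normalized_intensities
  floor_y <- y[length(y)]
  n_hi <- sum(target > y[1L])
  n_lo <- sum(target < floor_y)
  if (n_hi > 0) {
    warning(sprintf("%d target value(s) above 1 clamped to v_lo", n_hi), call. = FALSE)
  }
  if (n_lo > 0) {
    warning(sprintf("%d target value(s) below 1 - depth clamped to v_hi", n_lo),
            call. = FALSE)
  }
  tgt <- clamp(target, floor_y, y[1L])
  stats::approx(x = rev(y), y = rev(lut$voltages_v), xout = tgt)$y
}

#' Write a lookup table to CSV (with JSON sidecar)
#'
#' The CSV carries `voltage_v,normalized_intensity`; a `<path>.json` sidecar
#' records the channel, band bounds, and depth.
#'
#' @param lut A [build_lut()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lut_csv <- function(lut, path) {
  stopifnot(inherits(lut, "lookup_table"))
  utils::write.csv(
    data.frame(voltage_v = lut$voltages_v,
               normalized_intensity = lut$normalized_intensities),
    path, row.names = FALSE
  )
  jsonlite::write_json(
    list(channel = lut$channel, v_lo = lut$v_lo, v_hi = lut$v_hi,
         depth = lut$depth),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a lookup table written by [write_lut_csv()]
#' @param path CSV path (the `.json` sidecar must sit next to it).
#' @return A `lookup_table`.
#' @export
read_lut_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    list(channel = "", v_lo = df$voltage_v[1L],
         v_hi = df$voltage_v[nrow(df)],
         depth = 1 - df$normalized_intensity[nrow(df)])
  }
  structure(
    list(voltages_v = df$voltage_v,
         normalized_intensities = df$normalized_intensity,
         v_lo = meta$v_lo, v_hi = meta$v_hi, depth = meta$depth,
         channel = as.character(meta$channel)),
    class = "lookup_table"
  )
}

#' One-call channel characterization
#'
#' Convenience wrapper running the full calibration pass for one channel:
#' sweep, functional-range detection, and lookup-table construction.
#'
#' @inheritParams sweep_channel
#' @param drop_tolerance Passed to [find_functional_range()].
#' @return A `lookup_table`.
#' @export
characterize_channel <- function(phantom, channel_nm, v_start = 0.5,
                                 v_stop = 3.0, v_step = 0.05, n_repeats = 1,
                                 drop_tolerance = 0.002, seed = NULL) {
  curve <- sweep_channel(phantom, channel_nm, v_start, v_stop, v_step,
                         n_repeats, seed)
  band <- find_functional_range(curve, drop_tolerance)
  build_lut(curve, band[["v_lo"]], band[["v_hi"]])
}
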