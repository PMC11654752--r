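# Shared fixtures: everything is generated in code, nothing is stored.

# The four-channel noiseless phantom the studies run against.
fixture_phantom <- function() default_phantom()

# Characterized lookup table for one channel of the noiseless fixture.
fixture_lut <- function(wavelength_nm, phantom = fixture_phantom()) {
  characterize_channel(phantom, wavelength_nm)
}

# Independent brute-force trough scan: amplitude-gated raw local minima.
# Used as the oracle against segment_pulses; deliberately naive.
brute_force_troughs <- function(trace, level_frac = 0.1) {
  x <- trace$values
  n <- length(x)
  idx <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
  gate <- min(x) + level_frac * (max(x) - min(x))
  idx[x[idx] <= gate]
}

# Channel lookup without reaching into internals from every test.
get_channel_for_test <- function(phantom, wavelength_nm) {
  phantom$channels[[as.character(wavelength_nm)]]
}

# Copy a trace with new values (public constructor, same rate/start).
trace_like_for_test <- function(trace, values) {
  signal_trace(values, trace$sampling_rate_hz, trace$start_time_s,
               unit = trace$unit, label = trace$label)
}

# Constant-voltage trace helper.
const_voltage_trace <- function(v, n = 100, fs = 50) {
  signal_trace(rep(v, n), fs, unit = "V")
}
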