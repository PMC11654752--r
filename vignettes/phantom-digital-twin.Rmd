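---
title: "A digital twin of an LCD-modulated dynamic phantom for pulse oximetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital twin of an LCD-modulated dynamic phantom for pulse oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomtwin)
```

## The system being modeled

Dynamic tissue-mimicking phantoms give pulse oximeters and PPG
(photoplethysmography) monitors a controllable, reproducible "patient": an
optical element whose attenuation can be modulated electronically to imitate
the pulsatile blood-volume signal. In the hardware this package mirrors, a
broadband liquid-crystal display (LCD) sits in the light path behind a static
scattering silicone layer; the voltage applied to the LCD sets its
transmittance, and driving that voltage with a pulse-shaped waveform makes
the detected light intensity pulse like a PPG.

`phantomtwin` replaces every piece of that chain with a parametric software
model and keeps the *procedures* — characterization, lookup-table
construction, signal mapping, detection, and physiological-parameter
recovery — exactly as a hardware workflow would run them. The point is to be
able to exercise and validate the full pipeline (and any pulse-oximetry
algorithm sitting at its end) without the bench.

The optical hardware itself (light guide, collimation, mirror, photodiode
chain) is deliberately out of scope: everything between drive voltage and
detected intensity is abstracted into one transfer curve per wavelength.
The static layer's optical properties (absorption 0.1 cm^-1, reduced
scattering 10 cm^-1, 0.5 mm thickness) are carried as inert metadata only.

## The channel model

Each wavelength channel maps drive voltage to transmittance. Inside the
functional band $[v_{lo}, v_{hi}]$ the model uses a cosine ramp

$$T(v) = T_{open}\left(1 - d_{max}\,\frac{1 - \cos\!\big(\pi \tfrac{v - v_{lo}}{v_{hi} - v_{lo}}\big)}{2}\right),$$

which is smooth, strictly decreasing, and flat-ended at both band edges;
outside the band it continues linearly with a small positive tail slope so a
full sweep is non-monotone, as measured LCD responses are. Bench transfer
curves exist only as measurements, never as equations, so any
smooth strictly decreasing band shape is equally faithful; the cosine ramp
was chosen for having exact closed-form anchor points to test against
(`T(v_lo) = T_open`, `T(v_hi) = T_open (1 - d_max)`, half depth at the band
midpoint). A tabulated measured curve can be plugged in per channel instead
(`curve_table`), in which case it is linearly interpolated.

The default fixture carries the four characterized wavelengths with their
maximal modulation depths — 7% at 940 nm, 13% at 660 nm, 8% at 530 nm, and
2% at 455 nm — a shared 1.2–2.4 V functional band, open-state transmittance
0.9 (arbitrary: every downstream quantity is normalization-invariant, and a
property test verifies that), a DAC step of 1.526e-4 V (a 16-bit converter
spanning 10 V), and noiseless detection. Detector noise is additive Gaussian
expressed as a fraction of source intensity; shot-noise scaling is
deliberately not modeled. Source intensity and transmittance are in
arbitrary units throughout — absolute optical power never enters any
downstream result, which the calibration invariance tests confirm.

## Characterization and the lookup table

`sweep_channel()` steps the drive voltage over 0.5–3 V in 0.05 V increments
(51 points, averaging repeated measurements when noise is on).
`find_functional_range()` operationalizes "the range where intensity is
negatively correlated with voltage" as the longest contiguous decreasing run
of grid steps, where a step counts as decreasing only if it falls by more
than `drop_tolerance` (default 0.002) of the curve's global range — the
tolerance absorbs sensor noise, and ties between equal runs resolve toward
lower voltage. `build_lut()` then restricts the sweep to the band,
normalizes to the band maximum, and enforces a strictly decreasing profile.

Noisy sweeps can violate monotonicity, which inversion cannot tolerate, so
the lookup table applies isotonic regression (pool-adjacent-violators)
before a tie-breaking epsilon strictification. Inversion
(`lut_invert()`) is piecewise linear in both directions — the simplest
scheme consistent with the 0.05 V grid — and its error is tested against a
dense-grid brute-force inverse; on the default fixture the round-trip error
stays below 1e-3 in normalized intensity. Out-of-range targets clamp to the
band edges with a warning rather than erroring, since a normalized target
can exceed the table's floor by a hair of numerical noise.

## Waveform synthesis

The hardware study generated its PPG test signals with an external toolbox;
this package defines its own parametric morphology so the pipeline is
self-contained. Each beat is two positive Gaussian bumps on a baseline —
systolic (center 0.22 of the period, width 0.07, amplitude 1) and diastolic
(center 0.55, width 0.12, amplitude 0.35) — whose overlap produces the
dicrotic notch between them; an explicit notch dip is available but off by
default. These defaults were chosen once to give a realistic resting pulse
contour with clearly separated systolic/diastolic features; the exact pulse
shape of bench test waveforms is not specified anywhere, so only rate and
record-length properties are reproduced exactly.
With zero heart-rate jitter the waveform is exactly periodic (a property the
tests rely on); jitter, when enabled, perturbs each beat period by an i.i.d.
Gaussian factor under a fixed seed.

Resampling is linear interpolation at the new sample times — adequate for
smooth pulse shapes at the 50 Hz measurement rate used here, but with no
anti-alias filter, a documented limitation for broadband content. Depth
scaling (`scale_to_depth()`) maps the record's maximum to 1 and minimum to
$1 - d$, anchoring the non-pulsatile level at the top of the band; this
convention lets the 940 nm amplitude stay fixed while the 660 nm amplitude
is varied against the same DC level, as the saturation study requires.
A requested depth above a channel's ceiling raises an error rather than
silently flattening the waveform, because the 455 nm channel's 2% ceiling
sits close to the ~1% physiological perfusion index and silent clamping
would corrupt a study.

## Pulse segmentation and oximetry

Pulses are delimited trough to trough. Detection is peaks-first, the
standard PPG approach: systolic peaks are amplitude-gated local maxima
(upper 40% of the smoothed range) separated by at least $60/hr_{max}$
seconds, and each trough is the interior minimum between consecutive peaks.
Running the scan directly on raw local minima is not robust here — the
diastolic foot of this morphology is flat, so detector noise at the levels
the studies use can displace a raw argmin by tens of milliseconds, and the
dicrotic notch forms a second local minimum that a naive scan can mistake
for a trough. Three safeguards address this:

* detection runs on a lightly smoothed copy (80 ms centered moving
  average by default; configurable, 0 disables);
* trough times are refined by a basin centroid (samples below a low
  threshold around the minimum), which localizes a flat foot far better
  than the argmin;
* edge segments before the first and after the last peak contribute a
  trough only if their minimum lies clear of the record boundary *and* at
  the amplitude level of the interior troughs (median-based gate), so a
  partial trailing pulse whose lowest point is the dicrotic notch is
  discarded rather than mistaken for a pulse onset.

Each pulse reports its systolic maximum and its onset (leading-trough)
minimum, the usual convention for per-beat AC/DC extraction. The per-pulse
ratio of ratios is

$$R = \frac{\ln(I_{max,660}/I_{min,660})}{\ln(I_{max,940}/I_{min,940})},$$

and saturation follows the empirical linear calibration
$\mathrm{SpO_2} = -24.87\,R + 113.8$, stated for the 86–100% range; outputs
are reported unclipped with the validity range attached. The two channels
are segmented independently and pulses paired by index — the hardware
measured its channels one at a time, so strict simultaneity is not
available either way; a one-pulse count mismatch drops the unpaired
terminal pulse and larger mismatches are an error. Window averaging is the
arithmetic mean of per-pulse R over a 6 s window.

For study design the package also inverts the calibration:
`depth_for_spo2()` returns the 660 nm modulation depth that realizes a
target saturation against a fixed 940 nm depth, via the closed form
$d_{660} = 1 - (1 - d_{940})^{R}$ with $R$ from the calibration line. Its
correctness is tested against a numeric root solve of the R definition.

## The case studies

Both studies run the complete closed loop: synthesize at 1000 Hz, max
normalize, resample to the 50 Hz measurement rate, scale to depth, invert
through the lookup table, quantize to the DAC grid, detect with optional
noise, and recover the physiological parameter.

```{r hr-study}
hr <- run_hr_study(default_phantom(), noise_sd = 0.001, seed = 1)
head(hr$rows, 5)
sapply(hr$regressions, function(r) r$r_squared)
```

The heart-rate study covers 80–120 bpm in 10 bpm steps on all four channels
with 20 s records and 1% modulation depth — 1% because that is a typical
resting perfusion index and the largest depth the 2%-ceiling 455 nm channel
can comfortably express. The default study noise (0.1% of source intensity)
is a deliberately mild white-detector-noise level chosen as the package's
stand-in for bench noise; all noise magnitudes are exposed as arguments. Heart rate is
recovered as 60 over the mean inter-trough interval — equivalent, for these
clean periodic signals, to the toolbox rate estimators used on benches.

```{r spo2-study}
sp <- run_spo2_study(default_phantom(), seed = 1)
sp$rows[, c("spo2_programmed_percent", "mean_r", "r_expected",
            "spo2_recovered_percent")]
```

The saturation study drives both wavelengths from one shared normalized PPG
record — mirroring the single volunteer trace used on the bench, for which
a synthetic 75 bpm, 6 s record is substituted — at levels 86/90/95/100%
with the 940 nm depth fixed at its 7% channel maximum. The noiseless mean R
lands within 0.01 of the calibration ladder (1.12, 0.96, 0.76, 0.55) and
recovered saturation within 0.5 points of programmed.

```{r fidelity}
run_fidelity_check(default_phantom(), channel_nm = 455, depth = 0.01,
                   noise_sd = 5e-4, seed = 1)$average_error_percent
```

Reconstruction fidelity is scored as the mean absolute difference between
the max-normalized target and measured traces, in percentage points.
Noiselessly this is limited by lookup-table interpolation and DAC
quantization (below 0.01% on every channel at 1% depth); with noise it is
dominated by the noise itself plus the normalization's sensitivity to the
noisy record maximum.

## Numerical choices and reproducibility

All stochastic operations take a seed and restore the caller's RNG state;
the studies are bit-identical across runs with the same seed and
configuration. Study sizes (20 s records for heart rate, 6 s for
saturation, 51-point sweeps) match the protocol the package reproduces and
run in seconds. Degenerate inputs fail loudly: constant traces cannot be
depth-scaled or segmented, sweeps without a decreasing run of at least
three points have no functional range, bands narrower than three grid
points cannot form a lookup table, and zero 940 nm pulsatility makes R
undefined.

## What passing tests do and do not show

The synthetic generator emulates rate, record length, periodicity, pulse
contour (systolic peak, diastolic peak, dicrotic notch), perfusion-index
scale, and detector noise. It does not emulate real-tissue confounders:
baseline wander from respiration, motion artifacts (available only as
explicit injected disturbances via `add_noise()`), beat-morphology
variability, sensor coupling changes, or the wavelength dependence of real
blood absorption outside the two-wavelength linear regime. Closed-loop
recovery therefore validates the *pipeline* — characterization, mapping,
inversion, estimation, and their composition — not the clinical accuracy of
the linear calibration itself, which is taken as given and is only exact on
its stated 86–100% range.
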