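---
title: "Quantifying horse-rider movement synchronization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying horse-rider movement synchronization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During physical therapy that incorporates equine movement (hippotherapy), a
walking horse imparts a rhythmic, near-sinusoidal vertical motion to the
mounted rider at 90–100 impulses per minute. A clinically interesting question
is whether, over a course of sessions, the rider's body entrains to that
rhythm. `equisync` quantifies this from two body-worn inertial measurement
units (IMUs) — one on the horse's back, one on the rider's head — by reducing
each session to three interaction metrics computed on the vertical
acceleration (ACCz):

* **maximum lagged correlation** `max_corr`: the peak of the normalized
  cross-correlation between horse and rider ACCz, a temporal-synchronization
  measure in [-1, 1];
* **time shift** `lag_at_max`: the delay (seconds) of the rider signal
  producing that peak; positive means the rider's head lags the horse's back,
  as expected when the horse drives the rider;
* **harmonic RMSE** `rmse_freq`: the root-mean-square difference (Hz) between
  the dominant spectral peak frequencies of the two signals, a
  spatial-synchronization measure — zero when the rider's dominant rhythms sit
  exactly on the horse's gait harmonics.

Functional mobility (Timed Up and Go, 10-Meter Walk Test) is summarised
alongside as session-mean percent changes against session 1 and as group
standard deviations.

ACCz is used because vertical acceleration approximates the horse-rider
interaction force normalized by body mass, and the vertical direction carries
the dominant, gravity-loaded component of the gait impulse. The horse-back
signal is always the *reference*; the rider is modelled as responding to it.

## Processing model and assumptions

Each analysis session runs the same fixed pipeline:

1. **Alignment.** Both IMUs log on independent clocks at a nominal 100 Hz and
   share a single push-button sync pulse. `align_pair()` subtracts the pulse
   times (rider minus horse) and places both recordings on the horse clock.
   Multi-pulse clock-drift correction is out of scope; over a 10-minute
   window the drift of these loggers is well below one sample.
2. **Resampling.** All channels are linearly interpolated onto a shared
   uniform grid anchored at the analysis-window start. Linear interpolation is
   robust to log jitter and cannot overshoot; it reproduces affine signals
   exactly and preserves band-limited variance to within 1% when the rate is
   at least 4x the highest signal frequency.
3. **Vertical extraction.** By default the sensor's own z axis is taken
   (`sensor_z`), reproducing the convention of analysing raw ACCz without
   re-orientation. A `world_z` mode rotates each sample by the logged
   orientation quaternion first — offered because a head-mounted sensor tilts
   with the rider — but it requires the orientation channel and is not the
   default. The choice is recorded in the run log.
4. **Baseline removal.** Content below 1 Hz is gravity offset and slow
   posture drift, not gait; spectra exclude it via the analysis band, and the
   time-domain signals are high-passed at the same 1 Hz (4th-order
   Butterworth, applied forward-backward for zero phase shift) so the two
   metric families see the same signal. Odd-reflection padding suppresses the
   filter's edge transient. With `cutoff = 0` only the mean is subtracted.
5. **Windowing.** Only the first 10 minutes of each session — the continuous
   steady-walking phase — are analysed (`[pulse, pulse + 600 s)`, clipped to
   the common overlap; at least 60 s is required). Windows are half-open.

## The metrics

**Cross-correlation.** For every lag on the sample grid in ±`max_lag_s`
(default 2 s), the Pearson correlation between reference and shifted rider
signal is computed over the samples the two series share at that lag
(*overlap-only normalization*). Zero padding is deliberately avoided: it
biases |r| downward at large lags and distorts the location of the maximum.
The implementation uses an FFT convolution for the lagged cross-products and
cumulative sums for the per-lag means and variances; the test suite pins it
to a direct double-loop evaluation at 1e-9. Correlations are computed on the
full 10-minute window rather than averaged sub-windows — the simplest
defensible reading, and the lag estimate benefits from the longest possible
overlap. With periodic gait the correlation maximum recurs once per stride;
ties within 1e-9 resolve to the smallest |lag| (the physically minimal
transmission delay), then to the negative lag.

**Spectra.** Power spectral densities use Welch's method: 20 s Hann windows,
50% overlap, per-segment linear detrend. That gives 0.05 Hz resolution —
ample to separate the walk harmonics at 1.5, 3.0 and 4.5 Hz — and about 59
averaged segments per 10-minute session, enough to stabilise the noise floor.
The PSD is scaled so its integral over frequency estimates the variance
(checked by a Parseval test at 10%).

**Harmonic detection** searches local PSD maxima in a band of 1–6 Hz
(excluding the sub-1 Hz artifact region; capped above the 3rd harmonic's
plausible range). The fundamental is the most powerful in-band local maximum
after discarding candidates lying within ±30% of twice another
at-least-as-powerful candidate — this prevents a strong second harmonic from
being taken as the fundamental. The k-th harmonic is the most powerful local
maximum within ±30% of k times the fundamental; an empty window flags the
harmonic as missing rather than inventing a peak.

**Harmonic RMSE** is taken over peak *frequencies* (Hz), with pairs dropped
(and a warning raised) when either side's harmonic is missing. A peak-*power*
variant is available via `rmse_mode = "power"` for sensitivity analyses; the
frequency reading is the default because the quantity being summarised is
"how far the rider's dominant frequencies sit from the horse's", and it is
unit-stable across sensors with different gains.

**Functional trends.** Percent change of session means versus session 1 is
decrease-phrased for times, lag and RMSE (positive = improvement) and
increase-phrased for correlation. `percent_change()` pools pre- and
post-session tests by default — matching a single reported number per session
— while `functional_summary()` also reports the per-phase variants, since the
pooling convention is a genuine open choice. Group variability uses the
sample (n−1) standard deviation, the small-group convention. No hypothesis
tests are computed anywhere: with a handful of participants these are
descriptive summaries only.

## The synthetic-data generator

The generator provides ground truth the real study cannot: every metric can
be validated against known parameters.

* **Horse back** (`generate_horse_walk()`): gravity offset (9.81 m/s²) plus a
  harmonic series on the step-driven fundamental plus white noise. Defaults:
  cadence 90 steps/min (fundamental exactly 1.5 Hz, harmonics at 3.0 and
  4.5 Hz), amplitudes 1.0/0.5/0.25 m/s² — an invented but realistically
  decaying series producing the characteristic dominant-peaks spectrum —
  noise sd 0.1 m/s², 100 Hz, 600 s, sync pulse at t = 1 s.
* **Rider head** (`generate_rider_response()`): a linear gain (coupling 0–1)
  applied to the horse signal delayed by a pure transmission lag, plus an
  intrinsic-sway sinusoid uncorrelated with the horse, plus white noise. No
  biomechanical trunk model is attempted: gain + delay + independent sway is
  the simplest structure under which all three metrics are identifiable, and
  no quantitative rider-response model is available to emulate.
* **Progression** (`progression_config()`): across sessions 1–8 coupling
  rises 0.4 → 0.9, lag falls 0.5 → 0.2 s, rider noise falls 0.6 → 0.15 m/s²
  and sway falls 0.5 → 0.05 m/s² (all linear; sway at 2.2 Hz, away from any
  harmonic but inside the second harmonic's ±30% search window, so an
  uncoupled early-session rider realistically drags the detected harmonic off
  the horse's). Functional times are log-normal (positive, right-skewed) with
  log-scale parameters moment-matched to scheduled means/sds: TUG
  12.0/9.8/8.7 s and 10mWT 30.0/19.0/18.9 s at sessions 1/4/8 — declines of
  the size reported for these tests across an eight-session block.

What the generator does *not* emulate: walk-halt transitions (second session
half), 3-D horse kinematics, non-stationary cadence, sensor saturation or
orientation drift. Passing recovery tests therefore demonstrates the
correctness of the metrics under the assumed signal structure, not robustness
to every artifact of field recordings.

## Numerical choices and degenerate inputs

* Timestamps are seconds from device boot; the sync pulse makes absolute time
  irrelevant. Windows are half-open `[start, end)`; indices are handled on
  the sample grid throughout.
* Accelerometer units: logs default to g (converted by 9.80665), as
  Razor-class loggers commonly record; the simulator writes g so a
  simulate → analyze round trip is consistent by construction.
* Rows with non-numeric required fields are dropped and counted; parsing
  fails only when more than 5% of rows *and* more than 10 rows are dropped,
  so isolated corruption is tolerated without masking systematic failure.
* A correlation window with zero variance (a constant segment) yields r = 0
  for that lag rather than NaN; all r are clamped to [-1, 1] against
  floating-point spill.
* Quaternions are validated to unit norm (1e-6) and renormalised after
  interpolation.
* `remove_baseline` is idempotent up to the filter's passband droop (a second
  pass attenuates a 1.5 Hz tone by 3.8% with the default 1 Hz cutoff).
* Recordings shorter than 60 s of common overlap, windows outside the signal
  span, missing sync transitions, out-of-range sessions and duplicate
  manifest entries all fail with specific errors; per-session failures in a
  batch run are isolated and listed, not fatal.

## Problem sizes used in validation

The test suite exercises full-length (600 s) signals where the spectral
structure is the point, and 60–120 s signals for parameter-recovery loops
(lag-recovery grid: 3 lags x 2 couplings x 20 seeds; monotone-progression
recovery: 8 sessions x 20 seeds) — long enough that the 2 s maximum lag
leaves minutes of overlap and each Welch estimate averages several segments,
while keeping the whole suite under a minute of compute.

## Known limitations

* Synchronization is summarised by one correlation/lag/RMSE triple per
  session; time-varying (windowed or wavelet) measures, phase locking and
  coherence are out of scope, as are the anterior-posterior and
  medio-lateral axes.
* The ±30% harmonic windows assume a reasonably stable cadence; a horse that
  changes speed mid-session smears the peaks.
* `sensor_z` mode measures the head sensor's own z axis; systematic rider
  tilt leaks horizontal acceleration into it. `world_z` addresses this only
  when the logger's orientation estimate is trustworthy.
* Percent-change summaries are descriptive; no inferential claims are made
  or supported at these sample sizes.
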