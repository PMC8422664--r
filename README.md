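# equisync

Quantifying horse–rider movement interaction during physical therapy that
incorporates equine movement (hippotherapy), from paired body-worn IMU
recordings.

## The problem

A walking horse imparts a rhythmic vertical motion — roughly 90–100 impulses
per minute, i.e. a ~1.5 Hz fundamental with harmonics near 3.0 and 4.5 Hz —
to a mounted rider. Therapists using equine movement as a treatment tool want
to know whether the rider's body *entrains* to that rhythm over a course of
sessions, and whether entrainment tracks functional-mobility gains.
`equisync` answers the measurement half of that question for anyone analysing
dual-IMU (horse back + rider head) session recordings: rehabilitation
researchers, movement scientists and engineers building hippotherapy
instrumentation.

## What it computes

For each session, after sync-pulse alignment, resampling, vertical-channel
(ACCz) extraction and a 1 Hz zero-phase high-pass, with the horse-back signal
as the reference x(t) and the rider-head signal y(t):

* **Maximum lagged correlation** — the peak over lags τ ∈ [−2 s, +2 s] of the
  overlap-normalized Pearson correlation

  r(τ) = corr( x(t), y(t + τ) ),  r ∈ [−1, 1],

  and the **time shift** τ* = argmax r(τ) (positive = rider lags horse).
* **Harmonic RMSE** — with f₁…f_K the dominant peak frequencies of the
  horse's Welch PSD (20 s Hann windows, 50% overlap, harmonics searched in
  1–6 Hz, K = 3) and g₁…g_K the rider's,

  RMSE = √( (1/K) Σₖ (gₖ − fₖ)² )   [Hz].

* **Functional mobility trends** — Timed Up and Go / 10-Meter Walk Test
  session means, sample standard deviations, and percent changes of sessions
  4 and 8 versus session 1.

A synthetic generator (`generate_horse_walk()`, `generate_rider_response()`,
`generate_session_series()`) produces coupled horse–rider sessions with known
lag, coupling gain and progression, so every metric can be validated against
ground truth.

## Worked example

```r
library(equisync)

horse <- generate_horse_walk(horse_gait_config(duration_s = 120), seed = 1)
rider <- generate_rider_response(
  horse,
  rider_coupling_config(coupling_gain = 0.8, lag_s = 0.3,
                        rider_noise_sd = 0.3, sway_amp = 0.1),
  seed = 2)
pair <- align_pair(horse, rider, participant_id = "P1", session_index = 1)
m <- session_metrics(pair)
m
#> <sync_metrics> participant P1 session 1
#>   max r = 0.899 at lag +0.300 s; harmonic RMSE = 0.0000 Hz
m$harmonics_rider
#> <harmonic_set> fundamental 1.50 Hz; peaks: 1.50 Hz, 3.00 Hz, 4.50 Hz
```

The injected 0.3 s transmission delay is recovered exactly at the sample
grid; the correlation of 0.9 reflects the 0.8 coupling gain against the
rider's own noise and sway; and the rider's dominant peaks coincide with the
horse's gait harmonics, so the harmonic RMSE is 0 Hz — a fully entrained
(simulated) rider.

Batch runs go through the disk pipeline:

```r
sim <- run_simulate("dataset/", seed = 1)                  # CSV logs + manifest
res <- run_analyze(sim$manifest, sim$functional, "out/")   # metrics.csv, report.csv
```

`out/report.csv` lists percent changes of sessions 4 and 8 versus session 1
for the maximum correlation (increase-phrased), time shift, harmonic RMSE and
functional test times (decrease-phrased). A thin command-line wrapper is
installed at `inst/scripts/equisync.R`.

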