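# Independent oracles and fixture builders shared across the suite.

# Direct O(N * L) double-loop lagged Pearson correlation; the reference the
# FFT-accelerated implementation must match. Assumes both signals share t0.
brute_cross_correlation <- function(x, y, rate, max_lag) {
  n <- length(x)
  K <- round(max_lag * rate)
  ks <- (-K):K
  r <- vapply(ks, function(k) {
    if (k >= 0) {
      xi <- x[1:(n - k)]; yi <- y[(k + 1):n]
    } else {
      xi <- x[(1 - k):n]; yi <- y[1:(n + k)]
    }
    suppressWarnings(stats::cor(xi, yi))
  }, numeric(1))
  r[is.na(r)] <- 0
  list(lags = ks / rate, r = r)
}

# Exhaustive local-maximum scan over a PSD restricted to a frequency window.
brute_peak_in_window <- function(freqs, psd, lo, hi) {
  n <- length(psd)
  is_max <- c(FALSE, psd[2:(n - 1)] > psd[1:(n - 2)] & psd[2:(n - 1)] >= psd[3:n], FALSE)
  idx <- which(is_max & freqs >= lo & freqs <= hi)
  if (!length(idx)) return(NULL)
  idx[which.max(psd[idx])]
}

# Uniformly sampled sine as a baseline-removed vertical signal.
sine_signal <- function(freq, dur, rate = 100, amp = 1, phase = 0, t0 = 0,
                        placement = "horse_back") {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  v <- amp * sin(2 * pi * freq * t + phase)
  sig <- vertical_signal(t0, rate, v - mean(v), baseline_removed = TRUE,
                         source_placement = placement)
  sig
}

# Minimal IMU CSV on disk; returns the path.
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Small simulated recording pair for pipeline-level tests.
tiny_progression <- function(sessions = 1:3, duration_s = 90) {
  progression_config(
    sessions = sessions,
    coupling_gain = seq(0.5, 0.9, length.out = length(sessions)),
    lag_s = seq(0.4, 0.2, length.out = length(sessions)),
    rider_noise_sd = seq(0.4, 0.2, length.out = length(sessions)),
    sway_amp = seq(0.3, 0.05, length.out = length(sessions)),
    horse = horse_gait_config(duration_s = duration_s)
  )
}
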