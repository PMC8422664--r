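test_that("self-correlation is exactly 1 at lag 0 and -1 against the negation", {
  set.seed(21)
  rate <- 100
  v <- rnorm(30 * rate); v <- v - mean(v)
  x <- vertical_signal(0, rate, v, baseline_removed = TRUE)
  neg <- vertical_signal(0, rate, -v, baseline_removed = TRUE,
                         source_placement = "rider_head")
  prof <- cross_correlation(x, x, max_lag = 1)
  expect_equal(prof$r[prof$lags == 0], 1.0)
  prof_neg <- cross_correlation(x, neg, max_lag = 1)
  expect_equal(prof_neg$r[prof_neg$lags == 0], -1.0)
  expect_true(all(prof$r >= -1 & prof$r <= 1))
})

test_that("the FFT-accelerated profile matches the brute-force double loop", {
  rate <- 100
  cases <- list(
    delayed_sine = {
      t <- seq(0, 20 - 1 / rate, by = 1 / rate)
      list(x = sin(2 * pi * 1.5 * t), y = sin(2 * pi * 1.5 * (t - 0.2)))
    },
    noise = {
      set.seed(33)
      list(x = rnorm(1800), y = rnorm(1800))
    },
    mixed = {
      set.seed(34)
      t <- seq(0, 19.99, by = 1 / rate)
      s <- sin(2 * pi * 1.5 * t)
      list(x = s + 0.3 * rnorm(length(t)), y = 0.7 * s + 0.5 * rnorm(length(t)))
    }
  )
  for (nm in names(cases)) {
    x <- cases[[nm]]$x; y <- cases[[nm]]$y
    xs <- vertical_signal(0, rate, x - mean(x), baseline_removed = TRUE)
    ys <- vertical_signal(0, rate, y - mean(y), baseline_removed = TRUE,
                          source_placement = "rider_head")
    prof <- cross_correlation(xs, ys, max_lag = 2)
    oracle <- brute_cross_correlation(xs$values, ys$values, rate, 2)
    expect_equal(prof$lags, oracle$lags)
    expect_lt(max(abs(prof$r - oracle$r)), 1e-9)
  }
})

test_that("correlation stays in [-1, 1] for adversarial constant segments", {
  rate <- 100
  v <- c(rep(0, 1500), rnorm(1500)); v <- v - mean(v)
  w <- c(rnorm(1500), rep(0, 1500)); w <- w - mean(w)
  xs <- vertical_signal(0, rate, v, baseline_removed = TRUE)
  ys <- vertical_signal(0, rate, w, baseline_removed = TRUE,
                        source_placement = "rider_head")
  prof <- cross_correlation(xs, ys, max_lag = 2)
  expect_true(all(is.finite(prof$r)))
  expect_true(all(prof$r >= -1 & prof$r <= 1))
})

test_that("contract violations are rejected", {
  x <- vertical_signal(0, 100, rnorm(3000))
  y <- remove_baseline(x, 0)
  expect_error(cross_correlation(x, y, 1), "contract error")
  z <- vertical_signal(0, 50, rnorm(1500))
  z <- remove_baseline(z, 0)
  expect_error(cross_correlation(y, z, 1), "parameter error")
})

test_that("a noiseless delayed copy is recovered at the exact lag", {
  rate <- 100
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  for (lag in c(0.07, 0.20, 0.43)) {
    x <- sin(2 * pi * 1.3 * t) + 0.4 * sin(2 * pi * 2.6 * t + 0.5)
    y <- sin(2 * pi * 1.3 * (t - lag)) + 0.4 * sin(2 * pi * 2.6 * (t - lag) + 0.5)
    xs <- vertical_signal(0, rate, x - mean(x), baseline_removed = TRUE)
    ys <- vertical_signal(0, rate, y - mean(y), baseline_removed = TRUE,
                          source_placement = "rider_head")
    m <- max_corr_and_lag(cross_correlation(xs, ys, max_lag = 1))
    expect_equal(m$lag_at_max, lag, tolerance = 1 / rate + 1e-9)
    expect_gte(m$max_corr, 0.99)
  }
})

test_that("identical signals give (1, 0) and periodic ties resolve to lag 0", {
  rate <- 100
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  v <- sin(2 * pi * 1.25 * t)   # period 0.8 s sits exactly on the grid
  x <- vertical_signal(0, rate, v - mean(v), baseline_removed = TRUE)
  m <- max_corr_and_lag(cross_correlation(x, x, max_lag = 2))
  expect_equal(m$max_corr, 1.0)
  expect_equal(m$lag_at_max, 0)
})

test_that("welch_psd of a zero signal is identically zero", {
  sig <- vertical_signal(0, 100, rep(0, 5000), baseline_removed = TRUE)
  spec <- welch_psd(sig, window_s = 10)
  expect_true(all(spec$psd == 0))
  expect_equal(spec$resolution, 0.1)
})

test_that("welch_psd satisfies Parseval within 10% on band-limited noise", {
  set.seed(41)
  rate <- 100
  n <- 120 * rate
  white <- rnorm(n)
  bf <- signal::butter(4, c(0.02, 0.16))   # 1-8 Hz band at 100 Hz
  v <- signal::filtfilt(bf, white)
  v <- v / stats::sd(v)
  sig <- vertical_signal(0, rate, v - mean(v), baseline_removed = TRUE)
  spec <- welch_psd(sig, window_s = 20)
  integral <- sum(spec$psd) * spec$resolution
  expect_equal(integral, stats::var(v), tolerance = 0.1)
})

test_that("a pure tone yields a single dominant peak at its frequency", {
  rate <- 100
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  sig <- vertical_signal(0, rate, sin(2 * pi * 2 * t), baseline_removed = FALSE)
  sig <- remove_baseline(sig, 0)
  spec <- welch_psd(sig, window_s = 20)
  expect_equal(spec$freqs[which.max(spec$psd)], 2.0, tolerance = 0.05)
  too_short <- vertical_signal(0, rate, rnorm(10 * rate))
  expect_error(welch_psd(too_short, window_s = 20), "length error")
})

test_that("harmonic detection recovers the 1.5 / 3.0 / 4.5 Hz walk structure", {
  rate <- 100
  t <- seq(0, 120 - 1 / rate, by = 1 / rate)
  v <- sin(2 * pi * 1.5 * t) + 0.5 * sin(2 * pi * 3 * t) + 0.25 * sin(2 * pi * 4.5 * t)
  sig <- vertical_signal(0, rate, v - mean(v), baseline_removed = TRUE)
  spec <- welch_psd(sig, window_s = 20)
  hs <- detect_harmonics(spec, band = c(1, 6), K = 3)
  expect_equal(hs$fundamental, 1.5, tolerance = spec$resolution)
  expect_equal(hs$peak_freqs, c(1.5, 3.0, 4.5), tolerance = spec$resolution)
  expect_false(any(hs$missing))
  # peaks agree with an exhaustive local-maximum scan per harmonic window
  for (k in 1:3) {
    idx <- brute_peak_in_window(spec$freqs, spec$psd,
                                0.7 * k * hs$fundamental, 1.3 * k * hs$fundamental)
    expect_equal(hs$peak_freqs[k], spec$freqs[idx])
  }
})

test_that("a pure tone gives a one-peak harmonic set", {
  rate <- 100
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  sig <- vertical_signal(0, rate, sin(2 * pi * 2 * t) - mean(sin(2 * pi * 2 * t)),
                         baseline_removed = TRUE)
  hs <- detect_harmonics(welch_psd(sig, 20), band = c(1, 6), K = 1)
  expect_equal(hs$fundamental, 2.0, tolerance = 0.05)
})

test_that("an absent middle harmonic is flagged missing, others recovered", {
  rate <- 100
  t <- seq(0, 120 - 1 / rate, by = 1 / rate)
  v <- sin(2 * pi * 1.5 * t) + 0.4 * sin(2 * pi * 4.5 * t)
  sig <- vertical_signal(0, rate, v - mean(v), baseline_removed = TRUE)
  spec <- welch_psd(sig, window_s = 20)
  hs <- detect_harmonics(spec, band = c(1, 6), K = 3)
  expect_equal(hs$fundamental, 1.5, tolerance = spec$resolution)
  expect_true(hs$missing[2])
  expect_equal(hs$peak_freqs[3], 4.5, tolerance = spec$resolution)
  oracle2 <- brute_peak_in_window(spec$freqs, spec$psd, 0.7 * 3.0, 1.3 * 3.0)
  expect_null(oracle2)
})

test_that("a flat spectrum in the band raises a no-peak error", {
  spec <- structure(
    list(freqs = seq(0, 10, by = 0.05), psd = rep(1, 201), resolution = 0.05,
         window_meta = list()),
    class = "spectrum_welch"
  )
  expect_error(detect_harmonics(spec, band = c(1, 6), K = 3), "no-peak")
})

test_that("harmonic_rmse matches its closed form, is symmetric and scale-covariant", {
  mk <- function(freqs) structure(
    list(fundamental = freqs[1], peak_freqs = freqs,
         peak_powers = rep(1, length(freqs)),
         missing = rep(FALSE, length(freqs)), K = length(freqs)),
    class = "harmonic_set"
  )
  a <- mk(c(1.5, 3.0, 4.5))
  expect_equal(harmonic_rmse(a, a), 0.0)
  b <- mk(c(1.6, 3.1, 4.4))
  expect_equal(harmonic_rmse(a, b), 0.1, tolerance = 1e-12)
  set.seed(55)
  for (i in 1:10) {
    d <- rnorm(3, sd = 0.2)
    bb <- mk(c(1.5, 3.0, 4.5) + d)
    expect_equal(harmonic_rmse(a, bb), sqrt(mean(d^2)), tolerance = 1e-12)
    expect_equal(harmonic_rmse(a, bb), harmonic_rmse(bb, a))
    c_scaled <- mk(2 * (c(1.5, 3.0, 4.5) + d))
    a_scaled <- mk(2 * c(1.5, 3.0, 4.5))
    expect_equal(harmonic_rmse(a_scaled, c_scaled), 2 * harmonic_rmse(a, bb),
                 tolerance = 1e-12)
  }
})

test_that("missing harmonic pairs are dropped with a warning; all-missing errors", {
  mk <- function(freqs, missing) structure(
    list(fundamental = freqs[1], peak_freqs = ifelse(missing, NA, freqs),
         peak_powers = rep(1, length(freqs)), missing = missing,
         K = length(freqs)),
    class = "harmonic_set"
  )
  a <- mk(c(1.5, 3.0, 4.5), c(FALSE, TRUE, FALSE))
  b <- mk(c(1.6, 3.0, 4.4), c(FALSE, FALSE, FALSE))
  expect_warning(r <- harmonic_rmse(a, b), "missing")
  expect_equal(r, sqrt(mean(c(0.1, 0.1)^2)), tolerance = 1e-12)
  allm <- mk(c(1.5, 3.0, 4.5), rep(TRUE, 3))
  expect_error(suppressWarnings(harmonic_rmse(allm, b)), "undefined-metric")
})

test_that("session_metrics recovers an injected lag and degenerates correctly", {
  cfg <- horse_gait_config(duration_s = 120)
  horse <- generate_horse_walk(cfg, seed = 61)
  rider <- generate_rider_response(
    horse, rider_coupling_config(coupling_gain = 0.9, lag_s = 0.30,
                                 rider_noise_sd = 0.11, sway_amp = 0),
    seed = 62
  )
  pair <- align_pair(horse, rider, participant_id = "P1", session_index = 2)
  m <- session_metrics(pair)
  expect_equal(m$lag_at_max, 0.30, tolerance = 0.02)
  expect_gt(m$max_corr, 0.6)

  # rider replaced by the horse channel: exact degeneracy
  twin <- horse; twin$placement <- "rider_head"
  pair2 <- align_pair(horse, twin, participant_id = "P1", session_index = 2)
  m2 <- session_metrics(pair2)
  expect_equal(m2$max_corr, 1.0, tolerance = 1e-9)
  expect_equal(m2$lag_at_max, 0)
  expect_equal(m2$rmse_freq, 0)
})

test_that("an uncoupled rider shows near-zero correlation", {
  cfg <- horse_gait_config(duration_s = 600)
  horse <- generate_horse_walk(cfg, seed = 71)
  rider <- generate_rider_response(
    horse, rider_coupling_config(coupling_gain = 0, lag_s = 0,
                                 rider_noise_sd = 0.5, sway_amp = 0),
    seed = 72
  )
  pair <- align_pair(horse, rider, participant_id = "P1", session_index = 1)
  m <- session_metrics(pair)
  expect_lt(abs(m$max_corr), 0.1)
})
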