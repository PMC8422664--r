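test_that("resample_uniform places jittered samples on an exact grid", {
  set.seed(11)
  t <- sort(c(0, runif(120, 0, 1), 1))
  rec <- imu_recording(t, cbind(0, 0, sin(2 * pi * t)))
  out <- resample_uniform(rec, 100)
  expect_length(out$t, 101L)
  expect_equal(out$t, seq(0, 1, by = 0.01), tolerance = 1e-12)
})

test_that("resampling an already-uniform signal is the identity", {
  t <- seq(0, 2, by = 0.01)
  rec <- imu_recording(t, cbind(cos(t), sin(t), 9.81 + sin(3 * t)))
  out <- resample_uniform(rec, 100)
  expect_equal(out$acc, rec$acc, tolerance = 1e-9)
})

test_that("linear interpolation reproduces affine signals exactly at any rate", {
  set.seed(3)
  t <- sort(runif(200, 0, 5)); t <- c(0, t, 5)
  rec <- imu_recording(t, cbind(2 * t + 1, -t, t))
  for (rate in c(37, 100, 250)) {
    out <- resample_uniform(rec, rate)
    expect_equal(out$acc[, 3], out$t, tolerance = 1e-10)
    expect_equal(out$acc[, 1], 2 * out$t + 1, tolerance = 1e-10)
  }
  # mean of an affine signal is preserved exactly up to grid coverage
  expect_equal(mean(resample_uniform(rec, 100)$acc[, 1]),
               mean(2 * seq(0, 5, 0.01) + 1), tolerance = 1e-10)
})

test_that("resampling preserves band-limited variance within 1%", {
  rate0 <- 97  # deliberately awkward source rate
  t <- seq(0, 60, by = 1 / rate0)
  v <- sin(2 * pi * 1.5 * t) + 0.5 * sin(2 * pi * 4.5 * t + 1)
  rec <- imu_recording(t, cbind(0, 0, v))
  out <- resample_uniform(rec, 100)  # > 4x the highest frequency
  expect_equal(stats::var(out$acc[, 3]), stats::var(v), tolerance = 0.01)
})

test_that("extract_vertical honours sensor and world frames", {
  t <- seq(0, 1, by = 0.01); n <- length(t)
  # identity orientation: both modes agree
  quat_id <- cbind(rep(1, n), 0, 0, 0)
  rec <- imu_recording(t, cbind(0, 0, rep(9.81, n)), quat = quat_id)
  expect_equal(extract_vertical(rec, "sensor_z")$values, rep(9.81, n))
  expect_equal(extract_vertical(rec, "world_z")$values, rep(9.81, n),
               tolerance = 1e-12)

  # sensor rotated 90 deg about x measures gravity on its y axis
  s <- sqrt(0.5)
  quat_rot <- cbind(rep(s, n), s, 0, 0)
  rec_rot <- imu_recording(t, cbind(0, rep(9.81, n), 0), quat = quat_rot)
  expect_equal(extract_vertical(rec_rot, "world_z")$values, rep(9.81, n),
               tolerance = 1e-9)
  expect_equal(extract_vertical(rec_rot, "sensor_z")$values, rep(0, n))

  # zero input maps to zero output
  rec0 <- imu_recording(t, matrix(0, n, 3), quat = quat_rot)
  expect_equal(extract_vertical(rec0, "world_z")$values, rep(0, n))

  expect_error(extract_vertical(imu_recording(t, matrix(0, n, 3)), "world_z"),
               "missing-orientation")
})

test_that("world_z extraction is invariant to a constant mounting rotation", {
  t <- seq(0, 10, by = 0.01); n <- length(t)
  world_acc <- cbind(0.2 * sin(t), 0.1 * cos(2 * t), 9.81 + sin(2 * pi * 1.5 * t))
  # mounting rotation: 40 deg about axis (1, 2, 0.5)
  ax <- c(1, 2, 0.5); ax <- ax / sqrt(sum(ax^2)); th <- 40 * pi / 180
  q <- c(cos(th / 2), sin(th / 2) * ax)
  # sensor reading = world vector rotated into sensor frame (inverse rotation)
  qinv <- matrix(c(q[1], -q[2], -q[3], -q[4]), n, 4, byrow = TRUE)
  sensor_acc <- quat_rotate(qinv, world_acc)
  rec <- imu_recording(t, sensor_acc, quat = matrix(q, n, 4, byrow = TRUE))
  out <- extract_vertical(rec, "world_z")
  expect_equal(out$values, world_acc[, 3], tolerance = 1e-9)
})

test_that("remove_baseline with cutoff 0 subtracts the mean", {
  sig <- vertical_signal(0, 100, rep(9.81, 500))
  out <- remove_baseline(sig, cutoff = 0)
  expect_true(out$baseline_removed)
  expect_equal(out$values, rep(0, 500))

  set.seed(5)
  noisy <- vertical_signal(0, 100, rnorm(2000, mean = 3))
  expect_lt(abs(mean(remove_baseline(noisy, 0)$values)), 1e-12)
})

test_that("the 1 Hz high-pass removes gravity and keeps the 1.5 Hz gait tone", {
  rate <- 100
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  sig <- vertical_signal(0, rate, 9.81 + sin(2 * pi * 1.5 * t))
  out <- remove_baseline(sig, cutoff = 1.0)
  # RMS within 5% of the sine's own RMS
  expect_equal(sqrt(mean(out$values^2)), sqrt(0.5), tolerance = 0.05)
  # residual sub-1 Hz power below 1% of the total
  spec <- welch_psd(out, window_s = 20)
  low <- spec$freqs < 1
  expect_lt(sum(spec$psd[low]) / sum(spec$psd), 0.01)
})

test_that("remove_baseline is idempotent within numerical tolerance", {
  set.seed(9)
  rate <- 100
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  sig <- vertical_signal(0, rate, 9.81 + sin(2 * pi * 1.5 * t) + 0.3 * rnorm(length(t)))
  once <- remove_baseline(sig, 1.0)
  twice <- remove_baseline(once, 1.0)
  # compare away from the filter settle margin at the edges; the residual
  # difference is bounded by the zero-phase Butterworth passband droop at the
  # 1.5 Hz gait tone: a second pass attenuates it by 1 - |H(1.5)|^2 = 3.8%,
  # so the pointwise gap stays under ~0.04 for a unit-amplitude tone + noise
  core <- seq(3 * rate, length(once$values) - 3 * rate)
  expect_lt(max(abs(twice$values[core] - once$values[core])), 0.06)
})

test_that("remove_baseline rejects cutoffs at or above Nyquist", {
  sig <- vertical_signal(0, 100, rnorm(500))
  expect_error(remove_baseline(sig, 50), "parameter error")
})

test_that("crop_window keeps the half-open window and absolute time", {
  rate <- 100
  t <- seq(0, 700 - 1 / rate, by = 1 / rate)
  sig <- vertical_signal(0, rate, sin(t))
  out <- crop_window(sig, c(0, 600))
  expect_length(out$values, 60000L)
  expect_equal(out$t0, 0)

  full <- crop_window(sig, c(0, 700))
  expect_equal(full$values, sig$values)

  short <- vertical_signal(0, rate, sin(seq(0, 600, by = 1 / rate)))
  expect_error(crop_window(short, c(650, 700)), "window error")
})

test_that("cropping preserves phase: t0 reflects the window start", {
  rate <- 100
  t <- seq(0, 200 - 1 / rate, by = 1 / rate)
  sig <- vertical_signal(0, rate, sin(2 * pi * 1.5 * t))
  out <- crop_window(sig, c(70, 190))
  expect_equal(out$t0, 70)
  expect_equal(out$values[1], sin(2 * pi * 1.5 * 70), tolerance = 1e-9)
})
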