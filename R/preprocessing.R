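#' Construct a vertical-acceleration signal
#'
#' A `vertical_signal` is the uniformly sampled vertical acceleration (ACCz)
#' extracted from one sensor: start time `t0` (absolute session seconds),
#' sampling rate and a value vector in m/s^2. `baseline_removed` records
#' whether the gravity baseline has been taken out, a contract required by the
#' correlation stage.
#'
#' @param t0 Start time, seconds.
#' @param rate Sampling rate, Hz (> 0).
#' @param values Numeric vector of vertical accelerations, m/s^2.
#' @param baseline_removed Logical; when `TRUE` the values must have
#'   (numerically) zero mean.
#' @param source_placement `"horse_back"` or `"rider_head"`.
#' @return Object of class `vertical_signal`.
#' @export
vertical_signal <- function(t0, rate, values,
                            baseline_removed = FALSE,
                            source_placement = c("horse_back", "rider_head")) {
  source_placement <- match.arg(source_placement)
  values <- as.numeric(values)
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (any(!is.finite(values))) stop("signal values must be finite", call. = FALSE)
  if (baseline_removed) {
    tol <- 1e-6 * max(1, max(abs(values)))
    if (abs(mean(values)) > tol) {
      stop("baseline_removed signals must have zero mean", call. = FALSE)
    }
  }
  structure(
    list(t0 = as.numeric(t0), rate = as.numeric(rate), values = values,
         baseline_removed = isTRUE(baseline_removed),
         source_placement = source_placement),
    class = "vertical_signal"
  )
}

#' @export
print.vertical_signal <- function(x, ...) {
  cat(sprintf(
    "<vertical_signal> %s: %d samples at %g Hz, t0 = %.2f s, baseline %s\n",
    x$source_placement, length(x$values), x$rate, x$t0,
    if (x$baseline_removed) "removed" else "present"
  ))
  invisible(x)
}

#' Time axis of a vertical signal
#' @param sig A [vertical_signal].
#' @return Numeric vector of sample times, seconds.
#' @export
signal_time <- function(sig) {
  sig$t0 + (seq_along(sig$values) - 1L) / sig$rate
}

#' Resample a recording onto a uniform grid
#'
#' Linearly interpolates every channel onto the grid `t0 + k/rate`. By default
#' the grid is anchored at the first timestamp and spans the recording, giving
#' `floor((last - first) * rate) + 1` samples; an explicit anchor lets two
#' sensors be placed on a shared grid. Linear interpolation is used for all
#' channels (no overshoot, robust to log jitter); interpolated quaternions are
#' renormalised to unit length.
#'
#' @param rec An [imu_recording].
#' @param rate Target rate, Hz.
#' @param t0 Optional grid anchor (seconds). Grid points outside the
#'   recording's span are not generated.
#' @return A uniformly sampled [imu_recording].
#' @export
resample_uniform <- function(rec, rate, t0 = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!is.finite(rate) || rate <= 0) stop("parameter error: rate must be > 0", call. = FALSE)
  first <- rec$t[1]; last <- rec$t[length(rec$t)]
  if (is.null(t0)) {
    grid <- first + seq_len(floor((last - first) * rate + 1e-9) + 1L) / rate - 1 / rate
  } else {
    k0 <- ceiling((first - t0) * rate - 1e-9)
    k1 <- floor((last - t0) * rate + 1e-9)
    if (k1 < k0 + 1L) stop("resampling grid does not cover the recording", call. = FALSE)
    grid <- t0 + (k0:k1) / rate
  }
  interp <- function(y) stats::approx(rec$t, y, xout = grid, rule = 2)$y
  acc <- apply(rec$acc, 2, interp)
  gyro <- if (!is.null(rec$gyro)) apply(rec$gyro, 2, interp)
  quat <- if (!is.null(rec$quat)) {
    q <- apply(rec$quat, 2, interp)
    q / sqrt(rowSums(q^2))
  }
  sync <- if (!is.null(rec$sync)) {
    as.integer(stats::approx(rec$t, rec$sync, xout = grid, method = "constant",
                             rule = 2, f = 0)$y)
  }
  imu_recording(
    t = grid, acc = acc, gyro = gyro, quat = quat, sync = sync,
    sensor_id = rec$sensor_id, placement = rec$placement,
    nominal_rate = rate, dropped_rows = rec$dropped_rows
  )
}

is_uniform <- function(t, tol = 1e-6) {
  d <- diff(t)
  max(d) - min(d) <= tol * stats::median(d)
}

#' Extract the vertical acceleration channel
#'
#' Reduces a uniformly sampled recording to its vertical acceleration. In
#' `sensor_z` mode (the default and the convention used throughout the
#' analyses) the third accelerometer component is taken as-is. In `world_z`
#' mode each acceleration vector is rotated into the world frame using the
#' recording's orientation quaternions and the world vertical component is
#' taken — useful for a head-mounted sensor that tilts with the rider.
#'
#' @param rec A uniformly sampled [imu_recording].
#' @param frame_mode `"sensor_z"` or `"world_z"`.
#' @return A [vertical_signal] (baseline not yet removed).
#' @export
extract_vertical <- function(rec, frame_mode = c("sensor_z", "world_z")) {
  stopifnot(inherits(rec, "imu_recording"))
  frame_mode <- match.arg(frame_mode)
  if (!is_uniform(rec$t)) {
    stop("recording must be uniformly sampled; call resample_uniform() first",
         call. = FALSE)
  }
  rate <- 1 / stats::median(diff(rec$t))
  if (frame_mode == "sensor_z") {
    v <- rec$acc[, 3]
  } else {
    if (is.null(rec$quat)) {
      stop("missing-orientation error: world_z requires the quaternion channel",
           call. = FALSE)
    }
    v <- quat_rotate(rec$quat, rec$acc)[, 3]
  }
  vertical_signal(
    t0 = rec$t[1], rate = rate, values = v,
    baseline_removed = FALSE, source_placement = rec$placement
  )
}

#' Rotate sensor-frame vectors into the world frame
#'
#' Applies the rotation encoded by unit quaternions `q = (w, x, y, z)`
#' (sensor-to-world) to each row of `v`: `v_world = q v q*`.
#'
#' @param quat n x 4 matrix of unit quaternions.
#' @param v n x 3 matrix of sensor-frame vectors.
#' @return n x 3 matrix of world-frame vectors.
#' @export
quat_rotate <- function(quat, v) {
  quat <- as.matrix(quat); v <- as.matrix(v)
  w <- quat[, 1]; x <- quat[, 2]; y <- quat[, 3]; z <- quat[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 q_vec x v; v' = v + w t + q_vec x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(
    vx + w * tx + (y * tz - z * ty),
    vy + w * ty + (z * tx - x * tz),
    vz + w * tz + (x * ty - y * tx)
  )
}

#' Remove the gravity baseline from a vertical signal
#'
#' Spectral content below about 1 Hz in mounted-IMU vertical acceleration is
#' dominated by the constant gravity offset and slow posture drift rather than
#' gait, so it is removed before any correlation or spectral comparison. With
#' `cutoff = 0` only the mean is subtracted; with `cutoff > 0` a zero-phase
#' (forward-backward) 4th-order Butterworth high-pass at the cutoff is applied
#' first, then the residual mean is subtracted.
#'
#' @param sig A [vertical_signal].
#' @param cutoff High-pass cutoff, Hz; must satisfy `0 <= cutoff < rate / 2`.
#' @param order Butterworth order of the underlying one-pass filter.
#' @return A [vertical_signal] with `baseline_removed = TRUE`.
#' @export
remove_baseline <- function(sig, cutoff = 1.0, order = 4L) {
  stopifnot(inherits(sig, "vertical_signal"))
  if (cutoff < 0 || cutoff >= sig$rate / 2) {
    stop("parameter error: cutoff must lie in [0, rate/2)", call. = FALSE)
  }
  v <- sig$values
  if (cutoff > 0) {
    bf <- signal::butter(order, cutoff / (sig$rate / 2), type = "high")
    # odd-reflection padding keeps the forward-backward pass from ringing at
    # the recording edges (transient length ~ a few cutoff periods)
    n <- length(v)
    npad <- min(n - 1L, ceiling(3 * sig$rate / cutoff))
    v0 <- v - mean(v)
    padded <- c(2 * v0[1] - v0[seq(npad + 1L, 2L)],
                v0,
                2 * v0[n] - v0[seq(n - 1L, n - npad)])
    filtered <- signal::filtfilt(bf, padded)
    v <- filtered[npad + seq_len(n)]
  }
  v <- v - mean(v)
  vertical_signal(
    t0 = sig$t0, rate = sig$rate, values = v,
    baseline_removed = TRUE, source_placement = sig$source_placement
  )
}

#' Crop a signal to an analysis window
#'
#' Retains samples with `t` in the half-open window `[start, end)`. Timestamps
#' stay on the absolute session clock, so cropping never shifts the phase
#' relationship between the horse and rider signals.
#'
#' @param sig A [vertical_signal].
#' @param window Numeric `[start, end]`, seconds.
#' @param min_overlap_s Required overlap between window and signal span.
#' @return A cropped [vertical_signal].
#' @export
crop_window <- function(sig, window, min_overlap_s = 60) {
  stopifnot(inherits(sig, "vertical_signal"), length(window) == 2L)
  tt <- signal_time(sig)
  span_lo <- max(window[1], tt[1]); span_hi <- min(window[2], tt[length(tt)] + 1 / sig$rate)
  if (span_hi - span_lo < min_overlap_s) {
    stop(sprintf("window error: window overlaps signal by %.1f s (< %g s)",
                 max(0, span_hi - span_lo), min_overlap_s), call. = FALSE)
  }
  keep <- tt >= window[1] - 1e-9 & tt < window[2] - 1e-9
  out <- vertical_signal(
    t0 = tt[which(keep)[1]], rate = sig$rate, values = sig$values[keep],
    baseline_removed = FALSE, source_placement = sig$source_placement
  )
  # cropping a zero-mean signal leaves a (tiny) mean; keep the flag honest
  out$baseline_removed <- sig$baseline_removed
  out
}
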