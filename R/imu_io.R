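#' Default column mapping for Razor-style IMU CSV logs
#'
#' Maps the logical channels of a 9-DoF IMU log to the column names found in
#' the CSV file. Columns `t` (seconds) and `ax`, `ay`, `az` are required;
#' gyroscope, orientation quaternion and sync-pulse columns are optional.
#'
#' @return Named list of column names.
#' @export
default_column_map <- function() {
  list(
    t = "t",
    ax = "ax", ay = "ay", az = "az",
    gx = "gx", gy = "gy", gz = "gz",
    qw = "qw", qx = "qx", qy = "qy", qz = "qz",
    sync = "sync"
  )
}

#' Construct an IMU recording
#'
#' An `imu_recording` holds one sensor's timestamped 9-DoF log: timestamps in
#' seconds (strictly increasing), a per-sample 3-axis accelerometer matrix in
#' m/s^2, and optional gyroscope, orientation-quaternion and binary sync-pulse
#' channels. Two sensor placements are recognised: `"horse_back"` (the
#' reference signal in all interaction analyses) and `"rider_head"`.
#'
#' @param t Numeric vector of timestamps, seconds, strictly increasing.
#' @param acc n x 3 numeric matrix of accelerations, m/s^2.
#' @param gyro Optional n x 3 matrix of angular rates, rad/s.
#' @param quat Optional n x 4 matrix of unit quaternions (w, x, y, z).
#' @param sync Optional binary (0/1) sync-pulse vector of length n.
#' @param sensor_id Character label for the physical sensor.
#' @param placement One of `"rider_head"`, `"horse_back"`.
#' @param nominal_rate Nominal sampling rate in Hz; inferred from the median
#'   timestamp spacing when `NULL`.
#' @param dropped_rows Count of raw log rows discarded during parsing.
#' @return Object of class `imu_recording`.
#' @export
imu_recording <- function(t, acc, gyro = NULL, quat = NULL, sync = NULL,
                          sensor_id = "imu", placement = c("horse_back", "rider_head"),
                          nominal_rate = NULL, dropped_rows = 0L) {
  placement <- match.arg(placement)
  t <- as.numeric(t)
  acc <- as.matrix(acc)
  if (length(t) < 2L) {
    stop("empty-recording error: an imu_recording needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(t) || any(!is.finite(t))) {
    stop("timestamps must be finite", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("ordering error: timestamps must be strictly increasing", call. = FALSE)
  }
  if (ncol(acc) != 3L || nrow(acc) != length(t)) {
    stop("acc must be an n x 3 matrix matching the timestamps", call. = FALSE)
  }
  if (any(!is.finite(acc))) stop("acc values must be finite", call. = FALSE)
  if (!is.null(gyro)) {
    gyro <- as.matrix(gyro)
    stopifnot(ncol(gyro) == 3L, nrow(gyro) == length(t))
  }
  if (!is.null(quat)) {
    quat <- as.matrix(quat)
    stopifnot(ncol(quat) == 4L, nrow(quat) == length(t))
    norms <- sqrt(rowSums(quat^2))
    if (any(abs(norms - 1) > 1e-6)) {
      stop("orientation quaternions must have unit norm (within 1e-6)", call. = FALSE)
    }
  }
  if (!is.null(sync)) {
    sync <- as.integer(sync)
    stopifnot(length(sync) == length(t))
    if (!all(sync %in% c(0L, 1L))) stop("sync channel must be binary 0/1", call. = FALSE)
  }
  if (is.null(nominal_rate)) nominal_rate <- round(1 / stats::median(diff(t)))
  structure(
    list(
      sensor_id = sensor_id, placement = placement, t = t, acc = acc,
      gyro = gyro, quat = quat, sync = sync,
      nominal_rate = nominal_rate, dropped_rows = as.integer(dropped_rows)
    ),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  dur <- x$t[length(x$t)] - x$t[1]
  cat(sprintf(
    "<imu_recording> %s (%s)\n  %d samples, %.1f s at nominal %g Hz, t0 = %.3f s\n",
    x$sensor_id, x$placement, length(x$t), dur, x$nominal_rate, x$t[1]
  ))
  cat(sprintf(
    "  channels: acc%s%s%s; dropped rows: %d\n",
    if (!is.null(x$gyro)) " gyro" else "",
    if (!is.null(x$quat)) " quat" else "",
    if (!is.null(x$sync)) " sync" else "",
    x$dropped_rows
  ))
  invisible(x)
}

#' Read a Razor-style IMU CSV log
#'
#' Parses a comma-separated log (one header row, UTF-8) into an
#' [imu_recording]. Rows with a non-numeric value in any required column
#' (timestamp or accelerometer axis) are dropped and counted; optional
#' channels are kept only when all their mapped columns are present.
#' Accelerations logged in g are converted to m/s^2 (x 9.80665).
#'
#' @param path Path to the CSV file.
#' @param column_map Named list mapping logical channels to column names, see
#'   [default_column_map()].
#' @param acc_units Either `"g"` (default; converted by 9.80665 m/s^2 per g)
#'   or `"ms2"` for logs already in m/s^2.
#' @param placement,sensor_id Passed to [imu_recording()].
#' @param max_dropped_frac Parsing aborts when more than this fraction of rows
#'   (and more than 10 rows in absolute count) had to be dropped, so isolated
#'   log corruption is tolerated but systematic failure is not.
#' @return An [imu_recording].
#' @export
read_razor_log <- function(path, column_map = default_column_map(),
                           acc_units = c("g", "ms2"),
                           placement = c("horse_back", "rider_head"),
                           sensor_id = basename(path),
                           max_dropped_frac = 0.05) {
  acc_units <- match.arg(acc_units)
  placement <- match.arg(placement)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("t", "ax", "ay", "az")
  for (ch in required) {
    col <- column_map[[ch]]
    if (is.null(col) || !col %in% names(raw)) {
      stop(sprintf("format error: required column '%s' (channel %s) missing in %s",
                   if (is.null(col)) ch else col, ch, path), call. = FALSE)
    }
  }
  num <- function(ch) suppressWarnings(as.numeric(raw[[column_map[[ch]]]]))
  req <- cbind(t = num("t"), ax = num("ax"), ay = num("ay"), az = num("az"))
  keep <- rowSums(!is.finite(req)) == 0L
  dropped <- sum(!keep)
  if (sum(keep) < 2L) {
    stop("empty-recording error: fewer than 2 valid rows in ", path, call. = FALSE)
  }
  if (dropped > 10L && dropped / nrow(raw) > max_dropped_frac) {
    stop(sprintf("too many corrupt rows in %s: %d of %d dropped", path, dropped, nrow(raw)),
         call. = FALSE)
  }
  has_all <- function(chs) all(vapply(chs, function(ch) {
    col <- column_map[[ch]]
    !is.null(col) && col %in% names(raw)
  }, logical(1)))
  gyro <- if (has_all(c("gx", "gy", "gz"))) {
    cbind(num("gx"), num("gy"), num("gz"))[keep, , drop = FALSE]
  }
  quat <- if (has_all(c("qw", "qx", "qy", "qz"))) {
    cbind(num("qw"), num("qx"), num("qy"), num("qz"))[keep, , drop = FALSE]
  }
  sync <- if (has_all("sync")) round(num("sync"))[keep]
  scale <- if (acc_units == "g") 9.80665 else 1
  imu_recording(
    t = req[keep, "t"],
    acc = req[keep, c("ax", "ay", "az"), drop = FALSE] * scale,
    gyro = gyro, quat = quat, sync = sync,
    sensor_id = sensor_id, placement = placement, dropped_rows = dropped
  )
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_razor_log()]: emits a comma-separated log with the default
#' column names. Values are printed with 9 decimal places so a write/read
#' round trip reproduces every channel to at least 6 decimals.
#'
#' @param rec An [imu_recording].
#' @param path Output file path.
#' @param acc_units Units to write the accelerometer columns in.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path, acc_units = c("g", "ms2")) {
  acc_units <- match.arg(acc_units)
  stopifnot(inherits(rec, "imu_recording"))
  scale <- if (acc_units == "g") 1 / 9.80665 else 1
  df <- data.frame(
    t = rec$t,
    ax = rec$acc[, 1] * scale, ay = rec$acc[, 2] * scale, az = rec$acc[, 3] * scale
  )
  if (!is.null(rec$gyro)) {
    df$gx <- rec$gyro[, 1]; df$gy <- rec$gyro[, 2]; df$gz <- rec$gyro[, 3]
  }
  if (!is.null(rec$quat)) {
    df$qw <- rec$quat[, 1]; df$qx <- rec$quat[, 2]
    df$qy <- rec$quat[, 3]; df$qz <- rec$quat[, 4]
  }
  if (!is.null(rec$sync)) df$sync <- rec$sync
  num_cols <- setdiff(names(df), "sync")
  for (cn in num_cols) df[[cn]] <- sprintf("%.9f", df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect the shared push-button sync pulse
#'
#' Independently clocked IMUs are aligned on a single binary pulse triggered
#' by an external push button before the session. The pulse time is the
#' timestamp of the first 0 to 1 transition of the sync channel.
#'
#' @param rec An [imu_recording] with a sync channel.
#' @return Pulse time in seconds (on the recording's own clock).
#' @export
detect_sync_pulse <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  if (is.null(rec$sync)) {
    stop("missing-channel error: recording has no sync-pulse channel", call. = FALSE)
  }
  d <- diff(rec$sync)
  idx <- which(d == 1L)
  if (length(idx) == 0L) {
    stop("no-pulse error: sync channel contains no 0->1 transition", call. = FALSE)
  }
  rec$t[idx[1] + 1L]
}

#' Pair and time-align a horse and a rider recording
#'
#' Computes the clock offset between the two sensors from their sync pulses
#' (rider pulse time minus horse pulse time) and fixes the analysis window for
#' the session's continuous-riding phase. All times in the resulting
#' `session_pair` are on the horse's clock; downstream preprocessing shifts the
#' rider's timestamps by `-sync_offset` before any comparison. The window
#' defaults to the 10 minutes following the pulse, clipped to the common
#' overlap of the two recordings.
#'
#' @param horse,rider [imu_recording]s from the horse's back and rider's head.
#' @param window Optional `[start, end]` in seconds (horse clock); half-open
#'   `[start, end)` semantics apply downstream.
#' @param offset Optional explicit sync offset in seconds (rider clock minus
#'   horse clock), used when sync channels are absent.
#' @param participant_id,session_index Session metadata; `session_index` must
#'   lie in 1..8.
#' @param min_overlap_s Required common coverage after alignment, seconds.
#' @return Object of class `session_pair` with fields `horse`, `rider`,
#'   `sync_offset`, `analysis_window`, `participant_id`, `session_index`.
#' @export
align_pair <- function(horse, rider, window = NULL, offset = NULL,
                       participant_id = "unknown", session_index = 1L,
                       min_overlap_s = 60) {
  stopifnot(inherits(horse, "imu_recording"), inherits(rider, "imu_recording"))
  session_index <- as.integer(session_index)
  if (session_index < 1L || session_index > 8L) {
    stop("session_index must be in 1..8", call. = FALSE)
  }
  if (is.null(offset)) {
    horse_pulse <- detect_sync_pulse(horse)
    rider_pulse <- detect_sync_pulse(rider)
    offset <- rider_pulse - horse_pulse
  } else {
    horse_pulse <- horse$t[1]
  }
  # common coverage on the horse clock
  lo <- max(horse$t[1], rider$t[1] - offset)
  hi <- min(horse$t[length(horse$t)], rider$t[length(rider$t)] - offset)
  if (hi - lo < min_overlap_s) {
    stop(sprintf("insufficient-overlap error: recordings overlap by %.1f s (< %g s)",
                 hi - lo, min_overlap_s), call. = FALSE)
  }
  if (is.null(window)) {
    start <- max(lo, horse_pulse)
    window <- c(start, min(hi, start + 600))
  }
  if (window[2] - window[1] < min_overlap_s) {
    stop("insufficient-overlap error: analysis window shorter than minimum overlap",
         call. = FALSE)
  }
  structure(
    list(
      participant_id = participant_id, session_index = session_index,
      horse = horse, rider = rider,
      sync_offset = offset, analysis_window = as.numeric(window)
    ),
    class = "session_pair"
  )
}

#' @export
print.session_pair <- function(x, ...) {
  cat(sprintf(
    "<session_pair> participant %s, session %d\n  sync offset %.4f s, window [%.2f, %.2f) s\n",
    x$participant_id, x$session_index, x$sync_offset,
    x$analysis_window[1], x$analysis_window[2]
  ))
  invisible(x)
}

#' Load a session manifest
#'
#' A manifest is a YAML list of entries `{participant, session, horse_log,
#' rider_log, offset_override}` pointing at the per-session IMU logs. Entries
#' are validated (session in 1..8, files exist, no duplicate
#' participant/session) and returned in file order.
#'
#' @param path Path to the manifest YAML.
#' @param check_files When `TRUE` (default) referenced log files must exist.
#' @return `data.frame` with columns `participant`, `session`, `horse_log`,
#'   `rider_log`, `offset_override` (NA when absent).
#' @export
load_session_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  entries <- yaml::read_yaml(path)
  if (length(entries) == 0L) {
    warning("manifest is empty")
    return(data.frame(
      participant = character(), session = integer(),
      horse_log = character(), rider_log = character(),
      offset_override = numeric(), stringsAsFactors = FALSE
    ))
  }
  base <- dirname(normalizePath(path))
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    for (f in c("participant", "session", "horse_log", "rider_log")) {
      if (is.null(e[[f]])) {
        stop(sprintf("manifest entry %d is missing field '%s'", i, f), call. = FALSE)
      }
    }
    s <- as.integer(e$session)
    if (is.na(s) || s < 1L || s > 8L) {
      stop(sprintf("manifest entry %d: session_index %s outside 1..8", i, e$session),
           call. = FALSE)
    }
    resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
    data.frame(
      participant = as.character(e$participant), session = s,
      horse_log = resolve(e$horse_log), rider_log = resolve(e$rider_log),
      offset_override = if (is.null(e$offset_override)) NA_real_ else as.numeric(e$offset_override),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  dup <- duplicated(out[, c("participant", "session")])
  if (any(dup)) {
    stop("duplicate-entry error: repeated (participant, session): ",
         paste(sprintf("(%s, %d)", out$participant[dup], out$session[dup]), collapse = ", "),
         call. = FALSE)
  }
  if (check_files) {
    missing <- c(out$horse_log, out$rider_log)
    missing <- missing[!file.exists(missing)]
    if (length(missing)) {
      stop("path error: manifest references missing file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  out
}
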