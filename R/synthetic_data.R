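with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the simulated horse-back gait signal
#'
#' The vertical acceleration of a walking horse's back is modelled as a
#' harmonic series on the step-driven fundamental: with the default cadence of
#' 90 steps per minute the fundamental sits at 1.5 Hz, placing the first three
#' harmonics at 1.5, 3.0 and 4.5 Hz — the dominant peaks reported for
#' horse-and-rider vertical acceleration at a walk. Amplitudes default to a
#' decaying 1 : 0.5 : 0.25 m/s^2 series, giving a realistically decaying
#' harmonic spectrum on top of the gravity offset.
#'
#' @param cadence_spm Step cadence, steps per minute.
#' @param n_harmonics Number of harmonics.
#' @param amplitudes Per-harmonic amplitudes, m/s^2.
#' @param phases Per-harmonic phases, radians.
#' @param gravity_offset Constant vertical offset, m/s^2.
#' @param noise_sd Additive white measurement/gait-variability noise, m/s^2.
#' @param duration_s Recording length, seconds.
#' @param rate_hz Sampling rate, Hz.
#' @return Named list of class `horse_gait_config`.
#' @export
horse_gait_config <- function(cadence_spm = 90, n_harmonics = 3L,
                              amplitudes = c(1.0, 0.5, 0.25),
                              phases = c(0, 0.7, 1.3),
                              gravity_offset = 9.81, noise_sd = 0.1,
                              duration_s = 600, rate_hz = 100) {
  if (cadence_spm <= 0) stop("cadence_spm must be > 0", call. = FALSE)
  if (length(amplitudes) != n_harmonics || any(amplitudes <= 0)) {
    stop("amplitudes must be positive and of length n_harmonics", call. = FALSE)
  }
  if (length(phases) != n_harmonics) stop("phases must have length n_harmonics", call. = FALSE)
  structure(
    list(cadence_spm = cadence_spm, n_harmonics = as.integer(n_harmonics),
         amplitudes = amplitudes, phases = phases,
         gravity_offset = gravity_offset, noise_sd = noise_sd,
         duration_s = duration_s, rate_hz = rate_hz),
    class = "horse_gait_config"
  )
}

#' Configuration of the simulated rider response
#'
#' The rider's head is modelled as a delayed, attenuated copy of the
#' horse-back signal — a linear gain plus pure transmission delay — with an
#' additive intrinsic sway sinusoid (rider-generated motion uncorrelated with
#' the horse) and white noise. This is the simplest structure under which the
#' maximum correlation, the lag and the harmonic RMSE are all identifiable
#' against ground truth.
#'
#' @param coupling_gain Fraction of the horse motion transmitted, in `[0, 1]`.
#' @param lag_s Transmission delay, seconds (non-negative, below 2 s).
#' @param rider_noise_sd White-noise sd, m/s^2.
#' @param sway_amp Amplitude of the intrinsic sway, m/s^2.
#' @param sway_freq_hz Frequency of the intrinsic sway, Hz.
#' @return Named list of class `rider_coupling_config`.
#' @export
rider_coupling_config <- function(coupling_gain = 0.8, lag_s = 0.3,
                                  rider_noise_sd = 0.3,
                                  sway_amp = 0.1, sway_freq_hz = 2.2) {
  if (coupling_gain < 0 || coupling_gain > 1) {
    stop("validation error: coupling_gain must lie in [0, 1]", call. = FALSE)
  }
  if (lag_s < 0 || lag_s >= 2) stop("lag_s must lie in [0, 2) s", call. = FALSE)
  if (rider_noise_sd < 0 || sway_amp < 0) stop("noise and sway must be >= 0", call. = FALSE)
  structure(
    list(coupling_gain = coupling_gain, lag_s = lag_s,
         rider_noise_sd = rider_noise_sd, sway_amp = sway_amp,
         sway_freq_hz = sway_freq_hz),
    class = "rider_coupling_config"
  )
}

#' Session-over-session progression schedule
#'
#' Encodes the structure the longitudinal study design assumes: as sessions
#' progress the rider couples more strongly to the horse (gain up), responds
#' faster (lag down), and moves less on their own (noise and intrinsic sway
#' down), while functional mobility test times fall. Defaults span sessions
#' 1-8 with coupling 0.4 -> 0.9, lag 0.5 -> 0.2 s, rider noise 0.6 -> 0.15
#' m/s^2 and sway 0.5 -> 0.05 m/s^2, all linear in session number. The default
#' functional schedule has TUG means of 12.0 / 9.8 / 8.7 s and 10mWT means of
#' 30.0 / 19.0 / 18.9 s for sessions 1 / 4 / 8 — session-mean declines of the
#' size reported for these tests over an eight-session block.
#'
#' @param sessions Integer vector of session indices (within 1..8).
#' @param coupling_gain,lag_s,rider_noise_sd,sway_amp Per-session vectors
#'   (recycled scalars allowed).
#' @param sway_freq_hz Intrinsic sway frequency, Hz (shared).
#' @param horse Shared [horse_gait_config()].
#' @param functional `data.frame(test, session, mean_s, sd_s)` covering
#'   sessions 1, 4, 8 for each test to simulate.
#' @return List of class `progression_config` with a per-session
#'   `rider_coupling_config` schedule.
#' @export
progression_config <- function(sessions = 1:8,
                               coupling_gain = seq(0.4, 0.9, length.out = length(sessions)),
                               lag_s = seq(0.5, 0.2, length.out = length(sessions)),
                               rider_noise_sd = seq(0.6, 0.15, length.out = length(sessions)),
                               sway_amp = seq(0.5, 0.05, length.out = length(sessions)),
                               sway_freq_hz = 2.2,
                               horse = horse_gait_config(),
                               functional = default_functional_schedule()) {
  n <- length(sessions)
  rec <- function(v) rep_len(v, n)
  coupling_gain <- rec(coupling_gain); lag_s <- rec(lag_s)
  rider_noise_sd <- rec(rider_noise_sd); sway_amp <- rec(sway_amp)
  schedule <- lapply(seq_len(n), function(i) {
    rider_coupling_config(coupling_gain[i], lag_s[i], rider_noise_sd[i],
                          sway_amp[i], sway_freq_hz)
  })
  names(schedule) <- as.character(sessions)
  structure(
    list(sessions = as.integer(sessions), schedule = schedule,
         horse = horse, functional = functional),
    class = "progression_config"
  )
}

#' Default functional-test progression schedule
#'
#' @return `data.frame(test, session, mean_s, sd_s)` for TUG and 10mWT at
#'   sessions 1, 4 and 8.
#' @export
default_functional_schedule <- function() {
  data.frame(
    test = rep(c("TUG", "10mWT"), each = 3L),
    session = rep(c(1L, 4L, 8L), 2L),
    mean_s = c(12.0, 9.8, 8.7, 30.0, 19.0, 18.9),
    sd_s = c(3.5, 3.0, 2.5, 3.0, 2.0, 2.0),
    stringsAsFactors = FALSE
  )
}

#' Generate a simulated horse-back IMU recording
#'
#' Vertical channel: gravity offset plus the harmonic series of
#' [horse_gait_config()] plus white noise. Horizontal accelerometer channels
#' and the gyroscope carry low-amplitude noise; the sync pulse fires at t = 1 s.
#' Deterministic for a fixed `(cfg, seed)`.
#'
#' @param cfg A [horse_gait_config()].
#' @param seed Integer seed.
#' @return An [imu_recording] with `placement = "horse_back"`, acc in m/s^2.
#' @export
generate_horse_walk <- function(cfg = horse_gait_config(), seed = 1L) {
  stopifnot(inherits(cfg, "horse_gait_config"))
  with_seed(seed, {
    t <- seq(0, cfg$duration_s, by = 1 / cfg$rate_hz)
    n <- length(t)
    f0 <- cfg$cadence_spm / 60
    z <- rep(cfg$gravity_offset, n)
    for (k in seq_len(cfg$n_harmonics)) {
      z <- z + cfg$amplitudes[k] * sin(2 * pi * k * f0 * t + cfg$phases[k])
    }
    if (cfg$noise_sd > 0) z <- z + stats::rnorm(n, 0, cfg$noise_sd)
    lat_sd <- max(cfg$noise_sd, 0.02)
    acc <- cbind(stats::rnorm(n, 0, lat_sd), stats::rnorm(n, 0, lat_sd), z)
    gyro <- matrix(stats::rnorm(3 * n, 0, 0.01), ncol = 3)
    sync <- as.integer(t >= 1)
    imu_recording(
      t = t, acc = acc, gyro = gyro, sync = sync,
      sensor_id = sprintf("horse_sim_seed%d", seed), placement = "horse_back",
      nominal_rate = cfg$rate_hz
    )
  })
}

#' Generate the rider-head response to a horse recording
#'
#' Rider vertical channel: `gain * horse_z(t - lag)` (horse baseline removed
#' before delaying, gravity re-added afterwards) plus an intrinsic sway
#' sinusoid with a seed-drawn phase plus white noise. The sync pulse is shared
#' with the horse recording, as with a physical push-button trigger.
#'
#' @param horse An [imu_recording] from [generate_horse_walk()].
#' @param cfg A [rider_coupling_config()].
#' @param seed Integer seed.
#' @return An [imu_recording] with `placement = "rider_head"`.
#' @export
generate_rider_response <- function(horse, cfg = rider_coupling_config(), seed = 1L) {
  stopifnot(inherits(horse, "imu_recording"), inherits(cfg, "rider_coupling_config"))
  dur <- horse$t[length(horse$t)] - horse$t[1]
  if (cfg$lag_s >= dur) {
    stop("parameter error: lag_s must be shorter than the horse recording", call. = FALSE)
  }
  with_seed(seed, {
    t <- horse$t
    n <- length(t)
    hz <- horse$acc[, 3]
    gravity <- mean(hz)
    base <- hz - gravity
    delayed <- stats::approx(t, base, xout = t - cfg$lag_s, rule = 2)$y
    phase <- stats::runif(1, 0, 2 * pi)
    z <- gravity + cfg$coupling_gain * delayed +
      cfg$sway_amp * sin(2 * pi * cfg$sway_freq_hz * (t - t[1]) + phase)
    if (cfg$rider_noise_sd > 0) z <- z + stats::rnorm(n, 0, cfg$rider_noise_sd)
    lat_sd <- max(cfg$rider_noise_sd, 0.02)
    acc <- cbind(stats::rnorm(n, 0, lat_sd), stats::rnorm(n, 0, lat_sd), z)
    gyro <- matrix(stats::rnorm(3 * n, 0, 0.02), ncol = 3)
    imu_recording(
      t = t, acc = acc, gyro = gyro, sync = horse$sync,
      sensor_id = sprintf("rider_sim_seed%d", seed), placement = "rider_head",
      nominal_rate = horse$nominal_rate
    )
  })
}

#' Generate a full session series for one participant
#'
#' One aligned horse-rider [align_pair()] per scheduled session, with
#' independently seeded noise per session, plus the ground-truth coupling/lag
#' schedule used — the reference for parameter-recovery studies.
#'
#' @param prog A [progression_config()].
#' @param participant_id Participant label.
#' @param seed Integer base seed; per-session seeds are derived from it.
#' @return List with `pairs` (list of `session_pair`, one per session) and
#'   `truth` (`data.frame` of the per-session generator parameters).
#' @export
generate_session_series <- function(prog = progression_config(),
                                    participant_id = "P1", seed = 1L) {
  stopifnot(inherits(prog, "progression_config"))
  pairs <- vector("list", length(prog$sessions))
  truth <- vector("list", length(prog$sessions))
  pid_off <- sum(utf8ToInt(participant_id)) %% 1000L
  for (i in seq_along(prog$sessions)) {
    s <- prog$sessions[i]
    cfg <- prog$schedule[[as.character(s)]]
    horse_seed <- (seed + 7919L * pid_off + 101L * s) %% .Machine$integer.max
    horse <- generate_horse_walk(prog$horse, seed = horse_seed)
    rider <- generate_rider_response(horse, cfg, seed = horse_seed + 57L)
    pairs[[i]] <- align_pair(horse, rider, participant_id = participant_id,
                             session_index = s)
    truth[[i]] <- data.frame(
      participant = participant_id, session = s,
      coupling_gain = cfg$coupling_gain, lag_s = cfg$lag_s,
      rider_noise_sd = cfg$rider_noise_sd, sway_amp = cfg$sway_amp,
      sway_freq_hz = cfg$sway_freq_hz, stringsAsFactors = FALSE
    )
  }
  list(pairs = pairs, truth = do.call(rbind, truth))
}

#' Generate functional mobility test records
#'
#' Completion times are drawn from a log-normal distribution — times are
#' positive and right-skewed — with log-scale parameters moment-matched to the
#' scheduled session mean and sd, one pre and one post record per participant
#' and session. A zero-sd schedule reproduces the scheduled means exactly.
#'
#' @param prog A [progression_config()] whose `functional` schedule covers
#'   sessions 1, 4 and 8.
#' @param participants Named list mapping test name to participant labels,
#'   e.g. `list(TUG = c("P1", "P2", "P3"), "10mWT" = "P4")` (the default).
#' @param seed Integer seed.
#' @return A [functional_records] table.
#' @export
generate_functional_times <- function(prog = progression_config(),
                                      participants = list(
                                        TUG = c("P1", "P2", "P3"),
                                        "10mWT" = "P4"
                                      ),
                                      seed = 1L) {
  stopifnot(inherits(prog, "progression_config"))
  sched <- prog$functional
  for (test in names(participants)) {
    have <- sched$session[sched$test == test]
    if (!all(c(1L, 4L, 8L) %in% have)) {
      stop(sprintf("functional schedule for %s must cover sessions 1, 4 and 8", test),
           call. = FALSE)
    }
  }
  with_seed(seed, {
    rows <- list()
    for (test in names(participants)) {
      for (pid in participants[[test]]) {
        for (s in c(1L, 4L, 8L)) {
          row <- sched[sched$test == test & sched$session == s, ]
          m <- row$mean_s; sdev <- row$sd_s
          sigma2 <- log(1 + (sdev / m)^2)
          mu <- log(m) - sigma2 / 2
          for (ph in c("pre", "post")) {
            rows[[length(rows) + 1L]] <- data.frame(
              participant = pid, session = s, phase = ph, test = test,
              time_s = stats::rlnorm(1, mu, sqrt(sigma2)),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    functional_records(do.call(rbind, rows))
  })
}
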