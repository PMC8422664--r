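#' Lagged normalized cross-correlation between two vertical signals
#'
#' Treats the horse-back signal as the reference and evaluates, for every lag
#' tau on the sample grid in `[-max_lag, +max_lag]`, the Pearson correlation
#' between `ref(t)` and `target(t + tau)` over the samples the two series
#' share at that lag. Normalization uses only the overlapping samples (no
#' zero padding), so `|r|` is not biased downward at large lags and every
#' value lies in `[-1, 1]`. A positive lag at the maximum means the target
#' (rider's head) lags the reference (horse's back).
#'
#' Cross sums are computed with an FFT convolution and per-lag means and
#' variances with cumulative sums; the result matches a direct double-loop
#' evaluation to well below 1e-9 on signals of a few thousand samples.
#'
#' @param ref,target Baseline-removed [vertical_signal]s on the same rate and
#'   sample grid (grids may be offset by a whole number of samples).
#' @param max_lag Maximum absolute lag, seconds.
#' @param min_overlap_s Minimum overlap required at every lag, seconds.
#' @return Object of class `correlation_profile` with fields `lags` (seconds)
#'   and `r`.
#' @export
cross_correlation <- function(ref, target, max_lag = 2, min_overlap_s = 10) {
  stopifnot(inherits(ref, "vertical_signal"), inherits(target, "vertical_signal"))
  if (abs(ref$rate - target$rate) > 1e-6 * ref$rate) {
    stop("parameter error: ref and target must share a sampling rate", call. = FALSE)
  }
  if (!ref$baseline_removed || !target$baseline_removed) {
    stop("contract error: cross_correlation requires baseline-removed signals",
         call. = FALSE)
  }
  rate <- ref$rate
  shift <- (target$t0 - ref$t0) * rate
  if (abs(shift - round(shift)) > 1e-6) {
    stop("signals are not on a common sample grid; resample onto a shared anchor",
         call. = FALSE)
  }
  shift <- round(shift)
  # overlap in reference index space: target sample j sits at ref index j + shift
  i0 <- max(1L, 1L + shift)
  i1 <- min(length(ref$values), length(target$values) + shift)
  if (i1 - i0 + 1L < 2L) stop("signals do not overlap", call. = FALSE)
  x <- ref$values[i0:i1]
  y <- target$values[(i0 - shift):(i1 - shift)]
  n <- length(x)
  K <- round(max_lag * rate)
  if (n - K < min_overlap_s * rate) {
    stop(sprintf("overlap of %.1f s at the extreme lag is below the %g s minimum",
                 (n - K) / rate, min_overlap_s), call. = FALSE)
  }
  # Sxy(k) = sum_i x[i] y[i+k]; convolve(x, rev(y)) gives all of them at once
  cc <- stats::convolve(x, y, type = "open")  # index n - k holds Sxy(k)
  cx <- c(0, cumsum(x)); cx2 <- c(0, cumsum(x^2))
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y^2))
  ks <- (-K):K
  r <- vapply(ks, function(k) {
    if (k >= 0) {                      # pairs x[1..n-k] ~ y[k+1..n]
      nk <- n - k
      sx <- cx[nk + 1]; sxx <- cx2[nk + 1]
      sy <- cy[n + 1] - cy[k + 1]; syy <- cy2[n + 1] - cy2[k + 1]
    } else {                           # pairs x[1-k..n] ~ y[1..n+k]
      nk <- n + k
      sx <- cx[n + 1] - cx[-k + 1]; sxx <- cx2[n + 1] - cx2[-k + 1]
      sy <- cy[nk + 1]; syy <- cy2[nk + 1]
    }
    sxy <- cc[n - k]
    num <- sxy - sx * sy / nk
    den2 <- (sxx - sx^2 / nk) * (syy - sy^2 / nk)
    if (den2 <= .Machine$double.eps * nk) return(0)
    max(-1, min(1, num / sqrt(den2)))
  }, numeric(1))
  structure(list(lags = ks / rate, r = r, rate = rate), class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  m <- max_corr_and_lag(x)
  cat(sprintf(
    "<correlation_profile> %d lags in [%.2f, %.2f] s; max r = %.3f at %.3f s\n",
    length(x$lags), min(x$lags), max(x$lags), m$max_corr, m$lag_at_max
  ))
  invisible(x)
}

#' Maximum correlation and the time shift that produces it
#'
#' Finds the global maximum of a [cross_correlation()] profile and the lag at
#' which it occurs. With periodic gait signals the maximum can repeat once per
#' stride; ties (within 1e-9 in r) are broken in favour of the smallest
#' absolute lag — the physically minimal transmission delay — and, between a
#' negative and positive lag of equal size, the negative one.
#'
#' @param profile A `correlation_profile`.
#' @return List with `max_corr` and `lag_at_max` (seconds; positive = rider
#'   lags horse).
#' @export
max_corr_and_lag <- function(profile) {
  stopifnot(inherits(profile, "correlation_profile"))
  if (length(profile$r) == 0L) stop("empty correlation profile", call. = FALSE)
  rmax <- max(profile$r)
  cand <- which(profile$r >= rmax - 1e-9)
  lag <- profile$lags[cand]
  ord <- order(abs(lag), lag)      # smallest |lag|, negative before positive
  pick <- cand[ord[1]]
  list(max_corr = profile$r[pick], lag_at_max = profile$lags[pick])
}

#' Welch power spectral density of a vertical signal
#'
#' Averaged one-sided periodogram over Hann-tapered, overlapping,
#' per-segment linearly detrended segments. The frequency resolution is
#' `1/window_s`; the default 20 s window (0.05 Hz) comfortably separates the
#' walk harmonics near 1.5, 3.0 and 4.5 Hz. The density is scaled so that the
#' integral of the PSD over frequency estimates the signal variance.
#'
#' @param sig A [vertical_signal] at least `2 * window_s` long.
#' @param window_s Segment length, seconds.
#' @param overlap Segment overlap fraction in `[0, 1)`.
#' @param detrend Remove a per-segment linear trend before tapering.
#' @return Object of class `spectrum_welch` with fields `freqs` (Hz, 0 to
#'   Nyquist), `psd` (power per Hz), `resolution` (Hz) and `window_meta`.
#' @export
welch_psd <- function(sig, window_s = 20, overlap = 0.5, detrend = TRUE) {
  stopifnot(inherits(sig, "vertical_signal"))
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)", call. = FALSE)
  rate <- sig$rate
  L <- round(window_s * rate)
  n <- length(sig$values)
  if (n < 2 * L) {
    stop(sprintf("length error: signal (%d samples) must be at least 2 windows (%d)",
                 n, 2 * L), call. = FALSE)
  }
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)   # periodic Hann
  scale <- 1 / (rate * sum(w^2))
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  idx <- seq_len(L)
  k <- (idx - mean(idx))
  kk <- sum(k^2)
  for (s in starts) {
    seg <- sig$values[s + idx - 1L]
    if (detrend) {
      slope <- sum(k * seg) / kk
      seg <- seg - mean(seg) - slope * k
    }
    X <- stats::fft(seg * w)[seq_len(nf)]
    P <- (Re(X)^2 + Im(X)^2) * scale
    P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]
    if (L %% 2 == 1L) P[nf] <- 2 * P[nf]
    acc <- acc + P
  }
  structure(
    list(
      freqs = (seq_len(nf) - 1L) * rate / L,
      psd = acc / length(starts),
      resolution = rate / L,
      window_meta = list(window_s = L / rate, overlap = overlap, taper = "hann",
                         n_segments = length(starts), detrend = detrend)
    ),
    class = "spectrum_welch"
  )
}

#' @export
print.spectrum_welch <- function(x, ...) {
  cat(sprintf(
    "<spectrum_welch> %d bins, 0-%.1f Hz at %.3f Hz resolution (%d x %g s %s segments)\n",
    length(x$freqs), max(x$freqs), x$resolution,
    x$window_meta$n_segments, x$window_meta$window_s, x$window_meta$taper
  ))
  invisible(x)
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Detect the gait fundamental and its harmonics in a PSD
#'
#' Walking horses impart a near-sinusoidal vertical motion whose spectrum
#' shows peaks at integer multiples of the stride-driven fundamental (about
#' 1.5, 3.0, 4.5 Hz at a walk). Content below the lower band edge is treated
#' as gravity/posture artifact and ignored. The fundamental is the most
#' powerful local maximum in the band after discarding candidates that sit
#' within +/-30% of twice another at-least-as-powerful candidate (so a strong
#' second harmonic is not mistaken for the fundamental). The k-th harmonic is
#' the most powerful local maximum within +/-30% of `k * fundamental`; a
#' harmonic window containing no local maximum is flagged missing.
#'
#' @param spec A [welch_psd()] spectrum.
#' @param band `[f_lo, f_hi]` search band, Hz; `f_lo` must be at least the
#'   spectral resolution.
#' @param K Number of harmonics to report (fundamental included as k = 1).
#' @param tol_frac Half-width of each harmonic search window as a fraction of
#'   its centre frequency.
#' @return Object of class `harmonic_set`: `fundamental` (Hz), `peak_freqs`,
#'   `peak_powers` (length `K`, NA where missing), `missing` (logical), `K`.
#' @export
detect_harmonics <- function(spec, band = c(1, 6), K = 3L, tol_frac = 0.3) {
  stopifnot(inherits(spec, "spectrum_welch"), length(band) == 2L, K >= 1L)
  if (band[1] < spec$resolution) {
    stop("band lower edge must be at least the spectral resolution", call. = FALSE)
  }
  if (band[2] > max(spec$freqs)) stop("band exceeds the spectrum range", call. = FALSE)
  peaks_all <- local_maxima(spec$psd)
  in_band <- peaks_all[spec$freqs[peaks_all] >= band[1] & spec$freqs[peaks_all] <= band[2]]
  if (length(in_band) == 0L) {
    stop("no-peak error: no local maximum inside the search band", call. = FALSE)
  }
  f <- spec$freqs[in_band]; p <- spec$psd[in_band]
  is_overtone <- vapply(seq_along(in_band), function(i) {
    any(p >= p[i] & seq_along(in_band) != i & abs(f[i] - 2 * f) <= tol_frac * 2 * f)
  }, logical(1))
  fund_pool <- if (all(is_overtone)) seq_along(in_band) else which(!is_overtone)
  fundamental <- f[fund_pool[which.max(p[fund_pool])]]
  peak_freqs <- rep(NA_real_, K); peak_powers <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    centre <- k * fundamental
    win <- peaks_all[abs(spec$freqs[peaks_all] - centre) <= tol_frac * centre]
    if (length(win)) {
      best <- win[which.max(spec$psd[win])]
      peak_freqs[k] <- spec$freqs[best]
      peak_powers[k] <- spec$psd[best]
    }
  }
  structure(
    list(fundamental = fundamental, peak_freqs = peak_freqs,
         peak_powers = peak_powers, missing = is.na(peak_freqs), K = as.integer(K)),
    class = "harmonic_set"
  )
}

#' @export
print.harmonic_set <- function(x, ...) {
  cat(sprintf("<harmonic_set> fundamental %.2f Hz; peaks: %s\n",
              x$fundamental,
              paste(ifelse(x$missing, "missing",
                           sprintf("%.2f Hz", x$peak_freqs)), collapse = ", ")))
  invisible(x)
}

#' RMSE between rider and horse harmonic peaks
#'
#' Root-mean-square error between corresponding dominant-peak frequencies of
#' the two spectra (or, optionally, peak powers). A small frequency RMSE means
#' the rider's dominant rhythms sit at the horse's gait harmonics — spatial
#' synchronization. Harmonics flagged missing on either side are dropped in
#' pairs with a warning before the RMSE is taken.
#'
#' @param ref,target [detect_harmonics()] results with equal `K` (horse is the
#'   conventional reference).
#' @param mode `"freq"` (Hz, default) or `"power"`.
#' @return RMSE as a single number (Hz in frequency mode).
#' @export
harmonic_rmse <- function(ref, target, mode = c("freq", "power")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "harmonic_set"), inherits(target, "harmonic_set"))
  if (ref$K != target$K) stop("harmonic sets must have equal K", call. = FALSE)
  keep <- !(ref$missing | target$missing)
  if (any(!keep)) {
    warning(sprintf("dropping %d harmonic pair(s) with a missing peak", sum(!keep)))
  }
  if (!any(keep)) stop("undefined-metric error: no harmonic pairs remain", call. = FALSE)
  a <- if (mode == "freq") ref$peak_freqs else ref$peak_powers
  b <- if (mode == "freq") target$peak_freqs else target$peak_powers
  sqrt(mean((b[keep] - a[keep])^2))
}

#' Default analysis parameters for session metrics
#'
#' @param ... Overrides for any of: `resample_hz` (100), `frame_mode`
#'   (`"sensor_z"`), `highpass_hz` (1), `max_lag_s` (2), `welch_window_s`
#'   (20), `welch_overlap` (0.5), `band_hz` (`c(1, 6)`), `n_harmonics` (3),
#'   `rmse_mode` (`"freq"`).
#' @return Named list of parameters.
#' @export
metrics_params <- function(...) {
  p <- list(
    resample_hz = 100, frame_mode = "sensor_z", highpass_hz = 1,
    max_lag_s = 2, welch_window_s = 20, welch_overlap = 0.5,
    band_hz = c(1, 6), n_harmonics = 3L, rmse_mode = "freq"
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) over <- over[[1]]
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  p[names(over)] <- over
  p
}

#' Per-session synchronization metrics
#'
#' Runs the full interaction analysis for one aligned horse-rider session:
#' both recordings are shifted onto the horse clock, resampled onto a shared
#' uniform grid anchored at the analysis window, reduced to vertical
#' acceleration, high-passed to remove the gravity baseline, and cropped to
#' the continuous-riding window. The horse-back signal is the reference:
#' the function reports the maximum lagged correlation, the time shift at the
#' maximum (positive = rider lags horse) and the RMSE between the two sets of
#' dominant harmonic frequencies, together with all intermediate artifacts.
#'
#' @param pair A [align_pair()] session.
#' @param params A [metrics_params()] list.
#' @return Object of class `sync_metrics`; see
#'   [as.data.frame.sync_metrics()] for the flat export.
#' @export
session_metrics <- function(pair, params = metrics_params()) {
  stopifnot(inherits(pair, "session_pair"))
  ctx <- sprintf("participant %s session %d", pair$participant_id, pair$session_index)
  run <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s (%s): %s", what, ctx, conditionMessage(e)), call. = FALSE)
    })
  }
  win <- pair$analysis_window
  prep <- function(rec, tshift) {
    rec2 <- rec
    rec2$t <- rec$t - tshift
    rec2 <- resample_uniform(rec2, params$resample_hz, t0 = win[1])
    sig <- extract_vertical(rec2, params$frame_mode)
    sig <- remove_baseline(sig, cutoff = params$highpass_hz)
    crop_window(sig, win)
  }
  horse <- run("preprocessing horse", prep(pair$horse, 0))
  rider <- run("preprocessing rider", prep(pair$rider, pair$sync_offset))
  profile <- run("cross-correlation",
                 cross_correlation(horse, rider, max_lag = params$max_lag_s))
  ml <- max_corr_and_lag(profile)
  spec_h <- run("welch psd horse",
                welch_psd(horse, params$welch_window_s, params$welch_overlap))
  spec_r <- run("welch psd rider",
                welch_psd(rider, params$welch_window_s, params$welch_overlap))
  harm_h <- run("harmonic detection horse",
                detect_harmonics(spec_h, params$band_hz, params$n_harmonics))
  harm_r <- run("harmonic detection rider",
                detect_harmonics(spec_r, params$band_hz, params$n_harmonics))
  rmse <- run("harmonic rmse", harmonic_rmse(harm_h, harm_r, params$rmse_mode))
  structure(
    list(
      participant_id = pair$participant_id, session_index = pair$session_index,
      max_corr = ml$max_corr, lag_at_max = ml$lag_at_max, rmse_freq = rmse,
      harmonics_horse = harm_h, harmonics_rider = harm_r,
      profile = profile, spectra = list(horse = spec_h, rider = spec_r),
      signals = list(horse = horse, rider = rider),
      params = params
    ),
    class = "sync_metrics"
  )
}

#' @export
print.sync_metrics <- function(x, ...) {
  cat(sprintf(
    "<sync_metrics> participant %s session %d\n  max r = %.3f at lag %+.3f s; harmonic RMSE = %.4f Hz\n",
    x$participant_id, x$session_index, x$max_corr, x$lag_at_max, x$rmse_freq
  ))
  invisible(x)
}

#' Flatten session metrics to a one-row data frame
#'
#' @param x A [session_metrics()] result.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return One-row `data.frame` with identification, the three headline
#'   metrics and per-harmonic peak frequencies for both sensors.
#' @export
as.data.frame.sync_metrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  K <- x$harmonics_horse$K
  out <- data.frame(
    participant = x$participant_id, session = x$session_index,
    max_corr = x$max_corr, lag_s = x$lag_at_max, rmse_freq_hz = x$rmse_freq,
    fundamental_hz_horse = x$harmonics_horse$fundamental,
    fundamental_hz_rider = x$harmonics_rider$fundamental,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(K)) {
    out[[sprintf("harm%d_hz_horse", k)]] <- x$harmonics_horse$peak_freqs[k]
    out[[sprintf("harm%d_hz_rider", k)]] <- x$harmonics_rider$peak_freqs[k]
  }
  out
}
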