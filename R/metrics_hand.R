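# Per-trial hand-tracking metrics: spatial error, cross-correlation lag,
# lag-compensated residual error, velocity statistics, binned power spectra,
# approximate entropy, submovement count and onset latency.

#' Mean Euclidean distance between two 2D position series
#'
#' @param a,b matrices (or data.frames with `x`,`y`) of equal length, cm.
#' @return Time-averaged per-sample Euclidean distance, cm.
#' @export
mean_euclidean_distance <- function(a, b) {
  a <- .as_xy(a); b <- .as_xy(b)
  if (nrow(a) != nrow(b)) stop("'a' and 'b' must have the same length")
  if (nrow(a) < 1L) stop("empty series")
  mean(sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2))
}

#' Temporal lag between two 2D series by interleaved cross-correlation
#'
#' The x and y signals of each series are interleaved (x1, y1, x2, y2, ...)
#' and the normalized (Pearson) cross-correlation of the two interleaved
#' sequences is evaluated at every whole-sample shift of the original series
#' (two interleaved positions per step, so x always aligns with x and y with
#' y). The reported lag maximizes that correlation. A positive lag means `a`
#' trails `b`: with `a` the cursor and `b` the target, the lag is the
#' visuomotor delay. Shifted comparisons are truncated to the valid overlap;
#' the series are never wrapped around (the target patterns are periodic, so
#' wrapping would alias the lag onto the pattern period).
#'
#' Because Pearson correlation does not depend on sample order, the
#' interleaved correlation at a given shift equals the correlation of the
#' pooled per-axis overlaps; the implementation exploits this with an
#' FFT-based evaluation of all shifts that is algebraically identical to the
#' direct per-shift computation.
#'
#' @param a,b equal-length 2D position series (cm).
#' @param fs sampling rate, Hz.
#' @param max_lag_ms half-width of the lag search window, ms; must be less
#'   than half the series duration.
#' @return A list with `lag_ms` (at the native sample resolution) and `r`,
#'   the peak correlation.
#' @export
interleaved_xcorr_lag <- function(a, b, fs, max_lag_ms = 500) {
  a <- .as_xy(a); b <- .as_xy(b)
  n <- nrow(a)
  if (nrow(b) != n) stop("'a' and 'b' must have the same length")
  K <- round(max_lag_ms / 1000 * fs)
  if (K < 0 || K >= n / 2) stop("'max_lag_ms' must be below half the duration")
  if (stats::var(c(a)) == 0 || stats::var(c(b)) == 0)
    stop("constant (zero-variance) input: correlation undefined")

  M <- stats::nextn(n + K + 1L, 2)
  pad <- function(v) c(v, rep(0, M - n))
  cross <- function(u, v) { # S(k) = sum_j u[j+k] v[j], k = -K..K
    w <- Re(stats::fft(stats::fft(pad(u)) * Conj(stats::fft(pad(v))),
                       inverse = TRUE)) / M
    c(w[seq(M - K + 1L, M)], w[seq_len(K + 1L)])
  }
  ks <- seq.int(-K, K)
  S_ab <- cross(a[, 1], b[, 1]) + cross(a[, 2], b[, 2])

  # per-shift overlap sums via prefix sums (pooled over the two axes)
  cs <- function(v) c(0, cumsum(v))
  ca  <- cs(a[, 1]) + cs(a[, 2]);      cb  <- cs(b[, 1]) + cs(b[, 2])
  ca2 <- cs(a[, 1]^2) + cs(a[, 2]^2);  cb2 <- cs(b[, 1]^2) + cs(b[, 2]^2)
  len <- n - abs(ks)
  lo_a <- pmax(ks, 0L); lo_b <- pmax(-ks, 0L)   # overlap a[lo_a+1 ..], b[lo_b+1 ..]
  S_a  <- ca[lo_a + len + 1L] - ca[lo_a + 1L]
  S_b  <- cb[lo_b + len + 1L] - cb[lo_b + 1L]
  S_aa <- ca2[lo_a + len + 1L] - ca2[lo_a + 1L]
  S_bb <- cb2[lo_b + len + 1L] - cb2[lo_b + 1L]

  m2 <- 2 * len  # pooled sample count per shift
  num <- S_ab - S_a * S_b / m2
  den2 <- (S_aa - S_a^2 / m2) * (S_bb - S_b^2 / m2)
  r <- ifelse(den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  if (all(is.na(r))) stop("correlation undefined at every shift")
  best <- order(-r, abs(ks), na.last = TRUE)[1]  # ties: smallest |lag|
  list(lag_ms = ks[best] * 1000 / fs, r = r[best])
}

#' Mean cursor-target distance after compensating the temporal lag
#'
#' Shifts the cursor backward in time by `lag_ms` and computes the mean
#' Euclidean distance to the target over the remaining valid overlap. With
#' `lag_ms = 0` this equals [mean_euclidean_distance()]. The residual
#' distance isolates spatial tracking error from temporal delay.
#'
#' @param cursor,target equal-length 2D series, cm.
#' @param lag_ms temporal lag to remove, ms (rounded to whole samples).
#' @param fs sampling rate, Hz.
#' @return Residual mean distance, cm.
#' @export
lag_compensated_distance <- function(cursor, target, lag_ms, fs) {
  cursor <- .as_xy(cursor); target <- .as_xy(target)
  n <- nrow(cursor)
  if (nrow(target) != n) stop("series length mismatch")
  k <- round(lag_ms / 1000 * fs)
  if (abs(k) >= n) stop("|lag| exceeds the trial duration")
  if (n - abs(k) < n / 2) stop("lag leaves less than 50% of the trial overlapping")
  if (k >= 0) {
    mean_euclidean_distance(cursor[(1 + k):n, , drop = FALSE],
                            target[1:(n - k), , drop = FALSE])
  } else {
    mean_euclidean_distance(cursor[1:(n + k), , drop = FALSE],
                            target[(1 - k):n, , drop = FALSE])
  }
}

#' Tangential velocity of a 2D trajectory
#'
#' Positions are low-pass filtered (zero phase) and differentiated by central
#' differences; the speed is the magnitude of the resulting velocity vector.
#'
#' @param xy 2D position series, cm.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz cutoff of the smoothing filter, Hz (`Inf` disables it).
#' @return A list with `speed` (cm/s, per sample), `mean` and `sd`.
#' @export
tangential_velocity <- function(xy, fs, cutoff_hz = 10) {
  xy <- .as_xy(xy)
  if (nrow(xy) < 3L) stop("need at least 3 samples")
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be > 0")
  vx <- .derivative(lowpass(xy[, 1], cutoff_hz, fs), fs)
  vy <- .derivative(lowpass(xy[, 2], cutoff_hz, fs), fs)
  speed <- sqrt(vx^2 + vy^2)
  list(speed = speed, mean = mean(speed), sd = stats::sd(speed))
}

#' Binned power spectrum of a position signal
#'
#' Mean-removed one-sided periodogram aggregated onto a coarse frequency
#' grid: `n_bins` bins centered at `step_hz * k`, each `step_hz` wide. The
#' default 18 bins at a 0.11-Hz step cover 0.11-1.98 Hz, the band in which
#' visuomotor feedback corrections live. Bin values are mean power densities
#' (signal-units squared per Hz), so `sum(power) * step_hz` approximates the
#' variance of a signal whose energy is confined to the binned band.
#'
#' @param x position signal, cm.
#' @param fs sampling rate, Hz.
#' @param n_bins number of frequency bins.
#' @param step_hz bin width and spacing, Hz.
#' @return A data.frame with `freq` (bin centers, Hz) and `power`.
#' @export
power_spectrum_binned <- function(x, fs, n_bins = 18, step_hz = 0.11) {
  n <- length(x)
  if (n / fs < 9.1)
    stop(sprintf(
      "signal of %.3g s is too short: need >= 9.1 s to resolve the %.3g-Hz bin spacing",
      n / fs, step_hz))
  x <- x - mean(x)
  X <- stats::fft(x)
  df <- fs / n
  jmax <- floor(n / 2)
  dens <- 2 * Mod(X[seq(2, jmax + 1L)])^2 / (fs * n)  # one-sided density
  freq <- seq_len(jmax) * df
  centers <- step_hz * seq_len(n_bins)
  power <- vapply(centers, function(fc) {
    sel <- freq > fc - step_hz / 2 & freq <= fc + step_hz / 2
    sum(dens[sel]) * df / step_hz
  }, numeric(1))
  data.frame(freq = centers, power = power)
}

#' Approximate entropy (ApEn) of a time series
#'
#' The regularity statistic `Phi_m(r) - Phi_(m+1)(r)` with Chebyshev-distance
#' template matching, self-matches included: larger values indicate a less
#' predictable signal. Invariant under joint rescaling of the signal and the
#' tolerance `r`.
#'
#' @param x numeric series.
#' @param m embedding (template) length.
#' @param r matching tolerance, in signal units. The conventional choice is
#'   `0.2 * sd(x)` (the default).
#' @return ApEn, dimensionless, >= 0 up to numerical round-off.
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2L) stop("series too short for embedding length m")
  if (!is.numeric(r) || r < 0) stop("'r' must be >= 0")
  d0 <- abs(outer(x, x, "-"))
  phi <- function(mm) {
    nm <- n - mm + 1L
    D <- d0[seq_len(nm), seq_len(nm), drop = FALSE]
    if (mm > 1L) for (l in seq_len(mm - 1L))
      D <- pmax(D, d0[seq_len(nm) + l, seq_len(nm) + l, drop = FALSE])
    C <- rowSums(D <= r) / nm
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

#' Count submovements from tangential acceleration zero crossings
#'
#' Movement intermittency index: the number of sign changes of the (smoothed)
#' tangential acceleration, divided by two, on the reasoning that each
#' submovement is one acceleration phase followed by one deceleration phase.
#' Sign changes are counted with a hysteresis dead-band (a fraction of the
#' trial's peak tangential acceleration) so that sensor noise around zero
#' does not inflate the count; `deadband = 0` reproduces the literal
#' zero-crossing rule. An odd trailing crossing counts as a (partial)
#' submovement, so a single point-to-point reach counts as one.
#'
#' @param xy 2D cursor series, cm.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz velocity smoothing cutoff, Hz (see [tangential_velocity()]).
#' @param deadband hysteresis, as a fraction of peak |acceleration|.
#' @return Integer submovement count.
#' @export
count_submovements <- function(xy, fs, cutoff_hz = 10, deadband = 0.02) {
  xy <- .as_xy(xy)
  if (nrow(xy) < 5L) stop("need at least 5 samples")
  speed <- tangential_velocity(xy, fs, cutoff_hz)$speed
  acc <- .derivative(speed, fs)
  # the derivative is one-sided at the edges; drop the outermost 50 ms
  tr <- min(round(0.05 * fs), (length(acc) - 3L) %/% 2)
  if (tr > 0) acc <- acc[(tr + 1L):(length(acc) - tr)]
  peak <- max(abs(acc))
  # numerical guard: constant-speed motion has no genuine acceleration signal
  floor_band <- 1e-5 * fs * max(speed)
  if (peak <= floor_band) return(0L)
  band <- max(deadband * peak, floor_band)
  s <- sign(acc[abs(acc) > band])
  if (length(s) < 2L) return(0L)
  as.integer(ceiling(sum(diff(s) != 0) / 2))
}

#' Movement onset latency from a speed threshold
#'
#' Time of the first sample at which the speed crosses the threshold from
#' below.
#'
#' @param speed tangential speed series, cm/s.
#' @param fs sampling rate, Hz.
#' @param threshold onset threshold, cm/s (default 10).
#' @return Latency in ms, or `NA` if the threshold is never crossed.
#' @export
onset_latency <- function(speed, fs, threshold = 10) {
  if (!is.numeric(threshold) || threshold <= 0) stop("'threshold' must be > 0")
  if (length(speed) && speed[1] >= threshold) return(0)
  idx <- which(speed[-1] >= threshold & speed[-length(speed)] < threshold)
  if (!length(idx)) return(NA_real_)
  idx[1] / fs * 1000
}

#' Analysis parameters for hand-tracking metrics
#'
#' @param max_lag_ms lag search half-window for [interleaved_xcorr_lag()], ms.
#' @param vel_cutoff_hz velocity smoothing cutoff, Hz.
#' @param apen_m,apen_r_factor ApEn embedding length and tolerance factor
#'   (tolerance = factor times the SD of the analyzed signal).
#' @param apen_fs rate (Hz) to which position is decimated before ApEn; the
#'   statistic is O(N^2) in series length.
#' @param submovement_deadband hysteresis fraction for [count_submovements()].
#' @param onset_threshold onset speed threshold, cm/s.
#' @param psd_bins,psd_step_hz binned-spectrum grid.
#' @param start_trim_s seconds trimmed from the start of the trial before
#'   computing distance/lag/velocity metrics (0 keeps the whole trial; onset
#'   latency always uses the full trial).
#' @return A named list of parameters.
#' @export
hand_params <- function(max_lag_ms = 500, vel_cutoff_hz = 10,
                        apen_m = 2, apen_r_factor = 0.2, apen_fs = 100,
                        submovement_deadband = 0.02, onset_threshold = 10,
                        psd_bins = 18, psd_step_hz = 0.11, start_trim_s = 0) {
  list(max_lag_ms = max_lag_ms, vel_cutoff_hz = vel_cutoff_hz,
       apen_m = apen_m, apen_r_factor = apen_r_factor, apen_fs = apen_fs,
       submovement_deadband = submovement_deadband,
       onset_threshold = onset_threshold,
       psd_bins = psd_bins, psd_step_hz = psd_step_hz,
       start_trim_s = start_trim_s)
}

# Decimate a band-limited signal: zero-phase anti-alias low-pass, then
# subsample by the nearest integer factor.
.decimate <- function(x, fs, fs_out) {
  by <- floor(fs / fs_out)
  if (by <= 1) return(x)
  y <- lowpass(x, 0.4 * fs / by, fs)
  y[seq(1, length(x), by = by)]
}

#' Compute all hand-tracking metrics for one trial
#'
#' Bundles the per-trial hand metrics into one tidy row: raw cursor-target
#' distance, interleaved cross-correlation lag and peak r, residual distance
#' at that lag, mean/SD of cursor tangential velocity, per-axis approximate
#' entropy (on position decimated to `apen_fs`), submovement count, onset
#' latency, and the 18-bin power spectra of horizontal and vertical cursor
#' position (`psd_x_01..psd_x_18`, `psd_y_01..psd_y_18`).
#'
#' @param trial a trial object (see [simulate_trial()] or [read_trial()]).
#' @param params analysis parameters from [hand_params()].
#' @return A one-row data.frame.
#' @export
analyze_hand_trial <- function(trial, params = hand_params()) {
  stopifnot(inherits(trial, "vt_trial"))
  id <- sprintf("participant %s trial %s", trial$participant_id, trial$trial_index)
  tryCatch({
    fs <- trial$fs
    cursor <- trial$cursor; target <- trial$target
    i0 <- round(params$start_trim_s * fs)
    if (i0 > 0) {
      keep <- seq(i0 + 1L, nrow(cursor))
      cursor <- cursor[keep, , drop = FALSE]
      target <- target[keep, , drop = FALSE]
    }
    xc <- interleaved_xcorr_lag(cursor, target, fs, params$max_lag_ms)
    tv <- tangential_velocity(cursor, fs, params$vel_cutoff_hz)
    dx <- .decimate(cursor[, 1], fs, params$apen_fs)
    dy <- .decimate(cursor[, 2], fs, params$apen_fs)
    # the spectrum and the onset latency always use the full trial: the
    # former needs the whole duration to resolve the 0.11-Hz bin spacing,
    # the latter is defined by the pre-onset portion
    psd_x <- power_spectrum_binned(trial$cursor[, 1], fs, params$psd_bins,
                                   params$psd_step_hz)
    psd_y <- power_spectrum_binned(trial$cursor[, 2], fs, params$psd_bins,
                                   params$psd_step_hz)
    onset_tv <- tangential_velocity(trial$cursor, fs, params$vel_cutoff_hz)
    out <- data.frame(
      participant_id = trial$participant_id,
      sex = trial$sex,
      trial_index = trial$trial_index,
      pattern_id = trial$pattern_id,
      distance = mean_euclidean_distance(cursor, target),
      lag_ms = xc$lag_ms,
      xcorr_peak_r = xc$r,
      residual_distance = lag_compensated_distance(cursor, target, xc$lag_ms, fs),
      mean_tv = tv$mean,
      sd_tv = tv$sd,
      apen_x = approximate_entropy(dx, params$apen_m,
                                   params$apen_r_factor * stats::sd(dx)),
      apen_y = approximate_entropy(dy, params$apen_m,
                                   params$apen_r_factor * stats::sd(dy)),
      n_submovements = count_submovements(cursor, fs, params$vel_cutoff_hz,
                                          params$submovement_deadband),
      onset_latency_ms = onset_latency(onset_tv$speed, fs, params$onset_threshold),
      stringsAsFactors = FALSE)
    out[paste0("psd_x_", sprintf("%02d", seq_len(params$psd_bins)))] <-
      as.list(psd_x$power)
    out[paste0("psd_y_", sprintf("%02d", seq_len(params$psd_bins)))] <-
      as.list(psd_y$power)
    out
  }, error = function(e) stop(sprintf("[%s] %s", id, conditionMessage(e)),
                              call. = FALSE))
}
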