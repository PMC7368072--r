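# Per-trial gaze metrics: saccade detection, saccadic rate, smooth-pursuit
# gain, and eye-target distance/lag.

#' Gaze analysis parameters
#'
#' The saccade detector is a standard velocity-threshold scheme sized to a
#' task with a ~16 cm/s target (at a 57-cm viewing distance 1 cm is about 1
#' degree of visual angle, so 40 cm/s is roughly 40 deg/s): samples whose
#' tangential gaze velocity exceeds `peak_threshold` for at least
#' `min_duration_ms` seed a saccade; the interval is then extended outward
#' to the nearest local speed minimum or `extend_threshold` crossing
#' (bounded by `max_extend_ms`), intervals closer than `merge_gap_ms` are
#' merged, and detections displacing gaze by less than `min_amplitude_cm`
#' are dropped.
#'
#' @param peak_threshold saccade peak velocity threshold, cm/s.
#' @param extend_threshold onset/offset velocity threshold, cm/s.
#' @param min_duration_ms minimum time above `peak_threshold`, ms.
#' @param max_extend_ms cap on the onset/offset extension, ms; during active
#'   pursuit the gaze speed may never drop below `extend_threshold`, so the
#'   extension is bounded.
#' @param min_amplitude_cm minimum saccade displacement, cm.
#' @param merge_gap_ms intervals closer than this are merged, ms.
#' @param vel_cutoff_hz smoothing cutoff for gaze velocity, Hz (light, so
#'   saccade velocity peaks are preserved).
#' @param sp_vel_cutoff_hz smoothing cutoff used for pursuit-gain speeds, Hz.
#' @param guard_ms guard zone excluded around each saccade when desaccading.
#' @param max_lag_ms lag search window for the eye-target lag, ms.
#' @param start_trim_s seconds trimmed from the start of the trial before
#'   computing distance/lag/gain (0 keeps the whole trial).
#' @return A named list of parameters.
#' @export
gaze_params <- function(peak_threshold = 40, extend_threshold = 10,
                        min_duration_ms = 6, max_extend_ms = 25,
                        min_amplitude_cm = 0.3,
                        merge_gap_ms = 20, vel_cutoff_hz = 80,
                        sp_vel_cutoff_hz = 20, guard_ms = 10,
                        max_lag_ms = 500, start_trim_s = 0) {
  list(peak_threshold = peak_threshold, extend_threshold = extend_threshold,
       min_duration_ms = min_duration_ms, max_extend_ms = max_extend_ms,
       min_amplitude_cm = min_amplitude_cm, merge_gap_ms = merge_gap_ms,
       vel_cutoff_hz = vel_cutoff_hz, sp_vel_cutoff_hz = sp_vel_cutoff_hz,
       guard_ms = guard_ms, max_lag_ms = max_lag_ms,
       start_trim_s = start_trim_s)
}

#' Detect catch-up saccades in a gaze trace
#'
#' @param gaze 2D gaze position series, cm.
#' @param fs sampling rate, Hz; at least 250 Hz for reliable velocity
#'   thresholds.
#' @param params detector constants from [gaze_params()].
#' @return A data.frame with one row per saccade: `onset`, `offset` (sample
#'   indices, 1-based) and `onset_ms`, `offset_ms`; ordered, non-overlapping.
#' @export
detect_saccades <- function(gaze, fs, params = gaze_params()) {
  if (is.null(gaze)) stop("no gaze channel")
  gaze <- .as_xy(gaze)
  if (fs < 250) stop("'fs' must be >= 250 Hz for saccade detection")
  speed <- tangential_velocity(gaze, fs, params$vel_cutoff_hz)$speed
  n <- length(speed)
  above <- speed > params$peak_threshold
  if (!any(above)) return(.saccade_df(integer(0), integer(0), fs))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$min_duration_ms / 1000 * fs
  starts <- starts[keep]; ends <- ends[keep]
  # velocity is one-sided at the recording edges; candidates touching the
  # first/last 50 ms are boundary artifacts, not saccades
  edge <- round(0.05 * fs)
  ok <- starts > edge & ends < n - edge
  starts <- starts[ok]; ends <- ends[ok]
  if (!length(starts)) return(.saccade_df(integer(0), integer(0), fs))
  # extend each core outward to the nearest local speed minimum or
  # extend_threshold crossing, whichever comes first, within max_extend_ms
  ext <- as.integer(round(params$max_extend_ms / 1000 * fs))
  onset <- as.integer(vapply(starts, function(i) {
    lim <- max(1L, i - ext)
    while (i > lim && speed[i - 1L] <= speed[i] &&
           speed[i] >= params$extend_threshold) i <- i - 1L
    i
  }, numeric(1)))
  offset <- as.integer(vapply(ends, function(i) {
    lim <- min(n, i + ext)
    while (i < lim && speed[i + 1L] <= speed[i] &&
           speed[i] >= params$extend_threshold) i <- i + 1L
    i
  }, numeric(1)))
  # merge near-adjacent intervals
  gap <- params$merge_gap_ms / 1000 * fs
  mo <- onset[1]; mf <- offset[1]; outs <- integer(0); oute <- integer(0)
  if (length(onset) > 1L) for (i in seq.int(2L, length(onset))) {
    if (onset[i] - mf <= gap) mf <- max(mf, offset[i])
    else { outs <- c(outs, mo); oute <- c(oute, mf); mo <- onset[i]; mf <- offset[i] }
  }
  outs <- c(outs, mo); oute <- c(oute, mf)
  amp <- sqrt((gaze[oute, 1] - gaze[outs, 1])^2 +
                (gaze[oute, 2] - gaze[outs, 2])^2)
  keep <- amp >= params$min_amplitude_cm
  .saccade_df(outs[keep], oute[keep], fs)
}

.saccade_df <- function(onset, offset, fs) {
  data.frame(onset = onset, offset = offset,
             onset_ms = (onset - 1) / fs * 1000,
             offset_ms = (offset - 1) / fs * 1000)
}

#' Saccadic rate
#'
#' @param saccades a saccade table from [detect_saccades()].
#' @param duration_s trial duration, s.
#' @return Saccades per second.
#' @export
saccade_rate <- function(saccades, duration_s) {
  if (duration_s <= 0) stop("'duration_s' must be > 0")
  nrow(saccades) / duration_s
}

#' Smooth-pursuit gain
#'
#' Ratio of the mean gaze tangential speed to the mean target tangential
#' speed, computed over desaccaded samples only (detected saccade intervals
#' plus a guard zone are excluded). The ratio-of-means form is robust to
#' samples where the target speed is near zero.
#'
#' @param gaze,target equal-length 2D series, cm.
#' @param fs sampling rate, Hz.
#' @param saccades saccade table from [detect_saccades()].
#' @param params [gaze_params()] (uses `sp_vel_cutoff_hz` and `guard_ms`).
#' @return Pursuit gain, dimensionless.
#' @export
smooth_pursuit_gain <- function(gaze, target, fs, saccades,
                                params = gaze_params()) {
  gaze <- .as_xy(gaze); target <- .as_xy(target)
  n <- nrow(gaze)
  if (nrow(target) != n) stop("series length mismatch")
  keep <- rep(TRUE, n)
  guard <- round(params$guard_ms / 1000 * fs)
  if (nrow(saccades)) for (i in seq_len(nrow(saccades)))
    keep[max(1L, saccades$onset[i] - guard):min(n, saccades$offset[i] + guard)] <- FALSE
  if (mean(keep) < 0.5)
    stop("less than 50% of samples remain after desaccading")
  vg <- tangential_velocity(gaze, fs, params$sp_vel_cutoff_hz)$speed
  vt <- tangential_velocity(target, fs, params$sp_vel_cutoff_hz)$speed
  mean(vg[keep]) / mean(vt[keep])
}

#' Compute all gaze metrics for one trial
#'
#' Eye-target distance and lag are computed on the raw gaze signal, saccades
#' included (no desaccading distinction is drawn for these two metrics);
#' pursuit gain is computed on desaccaded samples.
#'
#' @param trial a `vt_trial` with a gaze channel.
#' @param params [gaze_params()].
#' @return A one-row data.frame: `eye_target_distance` (cm),
#'   `eye_target_lag_ms`, `eye_xcorr_peak_r`, `n_saccades`, `saccade_rate`
#'   (per s), `sp_gain`.
#' @export
analyze_gaze_trial <- function(trial, params = gaze_params()) {
  stopifnot(inherits(trial, "vt_trial"))
  if (is.null(trial$gaze)) stop(sprintf(
    "[participant %s trial %s] no gaze channel",
    trial$participant_id, trial$trial_index))
  id <- sprintf("participant %s trial %s", trial$participant_id, trial$trial_index)
  tryCatch({
    fs <- trial$fs
    gaze <- .as_xy(trial$gaze); target <- .as_xy(trial$target)
    i0 <- round(params$start_trim_s * fs)
    if (i0 > 0) {
      keep <- seq(i0 + 1L, nrow(gaze))
      gaze <- gaze[keep, , drop = FALSE]
      target <- target[keep, , drop = FALSE]
    }
    dur <- nrow(gaze) / fs
    sac <- detect_saccades(gaze, fs, params)
    xc <- interleaved_xcorr_lag(gaze, target, fs, params$max_lag_ms)
    data.frame(
      participant_id = trial$participant_id,
      sex = trial$sex,
      trial_index = trial$trial_index,
      pattern_id = trial$pattern_id,
      eye_target_distance = mean_euclidean_distance(gaze, target),
      eye_target_lag_ms = xc$lag_ms,
      eye_xcorr_peak_r = xc$r,
      n_saccades = nrow(sac),
      saccade_rate = saccade_rate(sac, dur),
      sp_gain = smooth_pursuit_gain(gaze, target, fs, sac, params),
      stringsAsFactors = FALSE)
  }, error = function(e) stop(sprintf("[%s] %s", id, conditionMessage(e)),
                              call. = FALSE))
}
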