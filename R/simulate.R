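# Generative simulator of visuo-oculo-manual tracking trials.
#
# Hand model: the cursor is a pure-delay copy of the target, smoothed by a
# zero-phase low-pass (so the configured delay is the net visuomotor lag),
# plus additive low-pass-filtered Gaussian positional noise; the cursor is
# held at its start position until the onset latency, then blends onto the
# moving trajectory with a minimum-jerk catch-up.
#
# Gaze model: smooth pursuit integrates a fixed gain times the delayed
# target velocity; position error therefore accumulates, and whenever the
# gaze-to-(delayed-)target error exceeds a threshold, a minimum-jerk
# catch-up saccade of fixed duration lands at a fixed fraction of the error
# vector.

#' Behavioral configuration of one simulated participant
#'
#' @param hand_lag_ms net visuomotor delay of the hand, ms.
#' @param hand_noise_sd SD of the tremor-band component of the additive
#'   positional noise per axis, cm (after band-limiting).
#' @param hand_cutoff_hz low-pass cutoff of the hand controller, Hz; the
#'   filter is zero-phase, so all of the temporal lag is carried by
#'   `hand_lag_ms`.
#' @param hand_noise_cutoff_hz band limit of the tremor noise, Hz.
#' @param hand_drift_sd SD of the slow spatial-drift noise component per
#'   axis, cm; drift contributes spatial error but little velocity, which is
#'   what lets a simulated participant show both a sizable residual error
#'   and modest velocity fluctuations, as humans do.
#' @param hand_drift_cutoff_hz band limit of the drift component, Hz.
#' @param onset_latency_ms time the cursor stays at its start position
#'   before tracking begins, ms.
#' @param onset_blend_ms duration of the minimum-jerk catch-up that joins
#'   the held cursor onto the moving trajectory, ms.
#' @param eye_lag_ms visuomotor delay of the eye, ms.
#' @param sp_gain smooth-pursuit velocity gain, in (0, 1].
#' @param saccade_threshold_cm gaze-target position error that triggers a
#'   catch-up saccade, cm.
#' @param saccade_duration_ms saccade duration, ms.
#' @param saccade_correction saccade landing rule: the saccade corrects the
#'   whole position error and, for values above 1, lands
#'   `(saccade_correction - 1) * |error|` ahead of the (delayed) target
#'   along its direction of motion. Human catch-up saccades are predictive
#'   in this way when pursuit gain is below 1: landing ahead lets the
#'   backward pursuit drift re-cross zero mid-interval, so the position
#'   error oscillates symmetrically around zero and the cross-correlation
#'   eye-target lag recovers the configured `eye_lag_ms` rather than
#'   `eye_lag_ms` plus half the drift. The default 1.95 was calibrated so
#'   that the recovered lag is unbiased to about 1 ms.
#' @param eye_noise_sd SD of additive gaze noise per axis, cm.
#' @param eye_noise_cutoff_hz band limit of the gaze noise, Hz.
#' @return An object of class `behavior_config`.
#' @export
behavior_config <- function(hand_lag_ms = 49, hand_noise_sd = 0.5,
                            hand_cutoff_hz = 1.5, hand_noise_cutoff_hz = 5.5,
                            hand_drift_sd = 1.0, hand_drift_cutoff_hz = 0.1,
                            onset_latency_ms = 325, onset_blend_ms = 300,
                            eye_lag_ms = 58, sp_gain = 0.80,
                            saccade_threshold_cm = 0.6,
                            saccade_duration_ms = 30,
                            saccade_correction = 1.95,
                            eye_noise_sd = 0.75, eye_noise_cutoff_hz = 1) {
  cfg <- list(hand_lag_ms = hand_lag_ms, hand_noise_sd = hand_noise_sd,
              hand_cutoff_hz = hand_cutoff_hz,
              hand_noise_cutoff_hz = hand_noise_cutoff_hz,
              hand_drift_sd = hand_drift_sd,
              hand_drift_cutoff_hz = hand_drift_cutoff_hz,
              onset_latency_ms = onset_latency_ms,
              onset_blend_ms = onset_blend_ms,
              eye_lag_ms = eye_lag_ms, sp_gain = sp_gain,
              saccade_threshold_cm = saccade_threshold_cm,
              saccade_duration_ms = saccade_duration_ms,
              saccade_correction = saccade_correction,
              eye_noise_sd = eye_noise_sd,
              eye_noise_cutoff_hz = eye_noise_cutoff_hz)
  .validate_behavior_config(cfg)
  structure(cfg, class = "behavior_config")
}

.validate_behavior_config <- function(cfg) {
  if (cfg$hand_lag_ms < 0 || cfg$eye_lag_ms < 0 || cfg$onset_latency_ms < 0)
    stop("lags and latencies must be >= 0")
  if (!(cfg$sp_gain > 0 && cfg$sp_gain <= 1))
    stop("'sp_gain' must lie in (0, 1]")
  if (cfg$saccade_threshold_cm <= 0) stop("'saccade_threshold_cm' must be > 0")
  if (cfg$hand_noise_sd < 0 || cfg$hand_drift_sd < 0 || cfg$eye_noise_sd < 0)
    stop("noise SDs must be >= 0")
  if (cfg$saccade_correction <= 0 || cfg$saccade_correction >= 2)
    stop("'saccade_correction' must lie in (0, 2)")
  invisible(cfg)
}

# Quintic smoothstep (minimum-jerk position profile), s in [0, 1].
.minjerk <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}

# Band-limited Gaussian noise scaled to a target per-axis SD, synthesized
# spectrally: white Gaussian spectrum shaped by the squared (zero-phase)
# magnitude response of a 2nd-order Butterworth low-pass. Stationary, with
# no filter edge transients. Two independent series (the two axes) are
# generated from one complex FFT.
.smooth_noise_pair <- function(n, sd_target, cutoff_hz, fs) {
  if (sd_target <= 0) return(matrix(0, n, 2))
  e <- stats::rnorm(n) + 1i * stats::rnorm(n)
  f <- pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) * fs / n
  h2 <- 1 / (1 + (f / cutoff_hz)^4)
  h2[1] <- 0  # zero-mean over the trial: constant offsets are not noise
  z <- stats::fft(stats::fft(e) * h2, inverse = TRUE) / n
  cbind(Re(z) / stats::sd(Re(z)), Im(z) / stats::sd(Im(z))) * sd_target
}

#' Simulate one eye/hand tracking trial
#'
#' @param pattern a [harmonic_pattern()] driving the target.
#' @param config a [behavior_config()].
#' @param duration trial duration, s.
#' @param fs sampling rate, Hz.
#' @param seed integer seed; the trial is bit-identical for equal seeds.
#' @param with_gaze simulate the gaze channel as well?
#' @param participant_id,sex,age,trial_index metadata carried on the trial.
#' @return A `vt_trial`: list with `time` (s), `target`, `cursor` and
#'   optionally `gaze` (n x 2 matrices, cm), `fs`, and the metadata.
#' @export
simulate_trial <- function(pattern, config, duration = 10, fs = 1000,
                           seed = 1, with_gaze = TRUE,
                           participant_id = "sim", sex = NA_character_,
                           age = NA_real_, trial_index = 1L) {
  stopifnot(inherits(pattern, "harmonic_pattern"))
  .validate_behavior_config(config)
  if (duration <= 0 || fs <= 0) stop("'duration' and 'fs' must be > 0")
  if (config$hand_lag_ms / 1000 >= duration)
    stop("'hand_lag_ms' must be shorter than the trial")
  set.seed(as.integer(seed %% 2147483647))
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  tg <- .target_cached(pattern, duration, fs, config$hand_cutoff_hz)

  cursor <- .simulate_hand(tg$smoothed, config, fs)
  gaze <- if (with_gaze) .simulate_gaze(tg$target, config, fs) else NULL

  structure(list(participant_id = participant_id, sex = sex, age = age,
                 trial_index = as.integer(trial_index),
                 pattern_id = pattern$pattern_id, fs = fs, time = tt,
                 target = tg$target, cursor = cursor, gaze = gaze),
            class = "vt_trial")
}

# Sampled target and its zero-phase-smoothed version, cached per pattern:
# both are deterministic given (pattern, duration, fs, cutoff).
.target_cache <- new.env(parent = emptyenv())

.target_cached <- function(pattern, duration, fs, cutoff_hz) {
  key <- paste(c(unlist(pattern), duration, fs, cutoff_hz), collapse = "_")
  hit <- .target_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- round(duration * fs)
  target <- target_position(pattern, (seq_len(n) - 1) / fs)
  smoothed <- cbind(lowpass(target[, 1], cutoff_hz, fs),
                    lowpass(target[, 2], cutoff_hz, fs))
  out <- list(target = target, smoothed = smoothed)
  .target_cache[[key]] <- out
  out
}

# The cursor tracks the smoothed target reference with a pure delay: the
# controller low-pass is zero-phase, so the configured delay is the net lag.
.simulate_hand <- function(sm_target, config, fs) {
  n <- nrow(sm_target)
  klag <- round(config$hand_lag_ms / 1000 * fs)
  g <- sm_target[pmax(1L, seq_len(n) - klag), , drop = FALSE]
  g <- g + .smooth_noise_pair(n, config$hand_noise_sd,
                              config$hand_noise_cutoff_hz, fs) +
    .smooth_noise_pair(n, config$hand_drift_sd,
                       config$hand_drift_cutoff_hz, fs)
  i_on <- round(config$onset_latency_ms / 1000 * fs)
  if (i_on > 0) {
    i_on <- min(i_on, n - 1L)
    nb <- max(1L, round(config$onset_blend_ms / 1000 * fs))
    c0 <- g[1, ]
    gap <- g[i_on + 1L, ] - c0
    w <- numeric(n)
    w[seq_len(i_on)] <- 1
    idx <- seq(i_on + 1L, min(n, i_on + nb))
    w[idx] <- 1 - .minjerk((idx - i_on - 1L) / nb)
    cursor <- g - outer(w, gap)
    cursor[seq_len(i_on), 1] <- c0[1]
    cursor[seq_len(i_on), 2] <- c0[2]
    cursor
  } else g
}

.simulate_gaze <- function(target, config, fs) {
  n <- nrow(target)
  keye <- round(config$eye_lag_ms / 1000 * fs)
  te <- target[pmax(1L, seq_len(n) - keye), , drop = FALSE]
  gain <- config$sp_gain
  thr <- config$saccade_threshold_cm
  dsac <- max(1L, round(config$saccade_duration_ms / 1000 * fs))
  g <- matrix(0, n, 2)
  g[1, ] <- te[1, ]
  i <- 1L
  while (i < n) {
    rest <- seq.int(i, n)
    px <- g[i, 1] + gain * (te[rest, 1] - te[i, 1])
    py <- g[i, 2] + gain * (te[rest, 2] - te[i, 2])
    err <- sqrt((te[rest, 1] - px)^2 + (te[rest, 2] - py)^2)
    hit <- which(err > thr)[1]
    if (is.na(hit)) { g[rest, 1] <- px; g[rest, 2] <- py; break }
    j <- i + hit - 1L
    seg <- seq_len(hit)
    g[rest[seg], 1] <- px[seg]; g[rest[seg], 2] <- py[seg]
    # predictive catch-up saccade: minimum-jerk jump that corrects the whole
    # error and lands ahead of the delayed target along its motion direction
    jend <- min(n, j + dsac)
    start <- g[j, ]
    errv <- te[j, ] - start
    jv <- min(n - 1L, max(2L, j))
    vte <- (te[jv + 1L, ] - te[jv - 1L, ]) * fs / 2   # delayed-target velocity
    vn <- sqrt(sum(vte^2))
    lead <- (config$saccade_correction - 1) * sqrt(sum(errv^2))
    # aim at where the delayed target will be at landing, plus the lead
    land <- if (vn > 1e-9) te[j, ] + vte * (jend - j) / fs + lead * vte / vn
      else start + config$saccade_correction * errv
    prof <- .minjerk((seq.int(j, jend) - j) / dsac)
    g[j:jend, 1] <- start[1] + prof * (land[1] - start[1])
    g[j:jend, 2] <- start[2] + prof * (land[2] - start[2])
    i <- jend
  }
  g + .smooth_noise_pair(n, config$eye_noise_sd, config$eye_noise_cutoff_hz, fs)
}

#' @export
print.vt_trial <- function(x, ...) {
  cat(sprintf("<vt_trial> participant %s (%s), trial %d, pattern %d\n",
              x$participant_id, x$sex, x$trial_index, x$pattern_id))
  cat(sprintf("  %d samples at %g Hz (%.3g s); gaze %s\n",
              length(x$time), x$fs, length(x$time) / x$fs,
              if (is.null(x$gaze)) "absent" else "present"))
  invisible(x)
}

#' Cohort-level simulation configuration
#'
#' Defines two groups of participants whose behavioral parameters are drawn
#' from sex-specific Gaussian distributions (truncated to valid ranges).
#' A latent per-participant "precision" factor is shared between eye and
#' hand with correlation `eye_hand_rho`, so that participants with accurate
#' eye tracking also tend to show accurate hand tracking.
#'
#' @param n_female,n_male group sizes.
#' @param trials_per_participant trials per participant; with
#'   `counterbalance = TRUE` it must be a multiple of the number of target
#'   patterns (each pattern is then tested equally often, order randomized).
#' @param female,male group-mean behavior ([behavior_config()]); the
#'   defaults differ only in the visuomotor delays and pursuit gain.
#' @param between_sd_female,between_sd_male named lists of
#'   between-participant SDs for any subset of
#'   `hand_lag_ms, hand_noise_sd, sp_gain, eye_lag_ms, saccade_threshold_cm,
#'   onset_latency_ms, eye_noise_sd`.
#' @param eye_hand_rho latent correlation (0-1) coupling eye and hand
#'   parameter draws within a participant.
#' @param age_mean_female,age_mean_male,age_sd_female,age_sd_male cohort age
#'   distributions, years.
#' @param duration_s,fs trial duration and sampling rate.
#' @param seed master seed. Participant-level draws come from one stream
#'   seeded with it; each trial then uses the derived sub-seed
#'   [trial_seed()], so any single trial is reproducible in isolation.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_female = 25, n_male = 25,
                          trials_per_participant = 10,
                          female = behavior_config(hand_lag_ms = 71,
                                                   eye_lag_ms = 60,
                                                   sp_gain = 0.82),
                          male = behavior_config(hand_lag_ms = 49,
                                                 eye_lag_ms = 58,
                                                 sp_gain = 0.80),
                          between_sd_female = list(
                            hand_lag_ms = 25, hand_noise_sd = 0.27,
                            sp_gain = 0.09, eye_lag_ms = 14,
                            saccade_threshold_cm = 0.13,
                            onset_latency_ms = 57, eye_noise_sd = 0.15),
                          between_sd_male = list(
                            hand_lag_ms = 21, hand_noise_sd = 0.22,
                            sp_gain = 0.08, eye_lag_ms = 13,
                            saccade_threshold_cm = 0.13,
                            onset_latency_ms = 55, eye_noise_sd = 0.15),
                          eye_hand_rho = 0.5,
                          age_mean_female = 25.5, age_mean_male = 25.5,
                          age_sd_female = 2.6, age_sd_male = 3.8,
                          duration_s = 10, fs = 1000, seed = 1) {
  if (n_female < 1 || n_male < 1) stop("group sizes must be >= 1")
  sds <- c(unlist(between_sd_female), unlist(between_sd_male))
  if (any(sds < 0)) stop("between-participant SDs must be >= 0")
  if (eye_hand_rho < 0 || eye_hand_rho > 1)
    stop("'eye_hand_rho' must lie in [0, 1]")
  structure(list(n_female = n_female, n_male = n_male,
                 trials_per_participant = trials_per_participant,
                 female = female, male = male,
                 between_sd_female = between_sd_female,
                 between_sd_male = between_sd_male,
                 eye_hand_rho = eye_hand_rho,
                 age_mean_female = age_mean_female,
                 age_mean_male = age_mean_male,
                 age_sd_female = age_sd_female, age_sd_male = age_sd_male,
                 duration_s = duration_s, fs = fs, seed = seed),
            class = "cohort_config")
}

#' Deterministic per-trial sub-seed
#'
#' Derived from the master seed by a fixed counter scheme so that any single
#' trial of a cohort can be re-simulated in isolation.
#'
#' @param master master seed (integer).
#' @param participant_index 1-based index of the participant in the cohort.
#' @param trial_index 1-based trial index.
#' @return An integer seed below 2^31.
#' @export
trial_seed <- function(master, participant_index, trial_index) {
  as.integer((as.numeric(master) * 1000003 +
                participant_index * 10007 + trial_index * 101) %% 2147483647)
}

# Draw one participant's behavior_config from group means/SDs.
# z_lag and z_acc are latent factors shared between eye and hand.
.draw_participant <- function(mean_cfg, sds, rho) {
  z_lag <- stats::rnorm(1); z_acc <- stats::rnorm(1)
  mix <- function(z) rho * z + sqrt(1 - rho^2) * stats::rnorm(1)
  dev <- function(field, z = NULL) {
    sd <- sds[[field]]
    if (is.null(sd) || sd == 0) return(0)
    sd * if (is.null(z)) stats::rnorm(1) else mix(z)
  }
  cfg <- mean_cfg
  cfg$hand_lag_ms <- max(5, cfg$hand_lag_ms + dev("hand_lag_ms", z_lag))
  cfg$eye_lag_ms <- max(5, cfg$eye_lag_ms + dev("eye_lag_ms", z_lag))
  # the hand_noise_sd between-SD is the SD of the total per-axis positional
  # noise; it rescales tremor and drift jointly
  tot <- sqrt(cfg$hand_noise_sd^2 + cfg$hand_drift_sd^2)
  scale <- max(0.05, (tot + dev("hand_noise_sd", z_acc)) / tot)
  cfg$hand_noise_sd <- cfg$hand_noise_sd * scale
  cfg$hand_drift_sd <- cfg$hand_drift_sd * scale
  cfg$saccade_threshold_cm <- max(0.2, cfg$saccade_threshold_cm +
                                    dev("saccade_threshold_cm", z_acc))
  cfg$eye_noise_sd <- max(0.02, cfg$eye_noise_sd + dev("eye_noise_sd", z_acc))
  cfg$sp_gain <- min(1, max(0.05, cfg$sp_gain + dev("sp_gain")))
  cfg$onset_latency_ms <- max(50, cfg$onset_latency_ms + dev("onset_latency_ms"))
  cfg
}

#' Simulate a whole cohort of tracking trials
#'
#' Draws per-participant behavioral parameters from the sex-specific
#' distributions in `config`, then simulates `trials_per_participant` trials
#' per participant with a randomized, counterbalanced pattern order (each of
#' the five standard patterns tested equally often). Fully deterministic
#' given the master seed.
#'
#' @param config a [cohort_config()].
#' @param with_gaze simulate the gaze channel? (A replication cohort with no
#'   eye tracker is simulated with `with_gaze = FALSE`.)
#' @param patterns list of target patterns (default: the packaged five).
#' @param counterbalance require the trial count to spread evenly over the
#'   patterns?
#' @return A list with `trials` (list of `vt_trial`) and `manifest` (one row
#'   per participant: id, sex, age, and the drawn behavioral parameters).
#' @export
simulate_cohort <- function(config, with_gaze = TRUE,
                            patterns = load_pattern_table(),
                            counterbalance = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  npat <- length(patterns)
  ntr <- config$trials_per_participant
  if (counterbalance && ntr %% npat != 0)
    stop(sprintf(
      "trials_per_participant (%d) must be a multiple of the %d patterns for counterbalancing",
      ntr, npat))
  set.seed(as.integer(config$seed %% 2147483647))
  n_all <- config$n_female + config$n_male
  sexes <- rep(c("F", "M"), c(config$n_female, config$n_male))
  ids <- sprintf("%s%02d", sexes, c(seq_len(config$n_female),
                                    seq_len(config$n_male)))
  draws <- vector("list", n_all)
  ages <- numeric(n_all)
  orders <- vector("list", n_all)
  for (p in seq_len(n_all)) {   # all participant-level draws: master stream
    f <- sexes[p] == "F"
    draws[[p]] <- .draw_participant(
      if (f) config$female else config$male,
      if (f) config$between_sd_female else config$between_sd_male,
      config$eye_hand_rho)
    ages[p] <- stats::rnorm(1, if (f) config$age_mean_female else config$age_mean_male,
                            if (f) config$age_sd_female else config$age_sd_male)
    orders[[p]] <- if (counterbalance)
      sample(rep(seq_len(npat), ntr / npat)) else
        sample(seq_len(npat), ntr, replace = TRUE)
  }
  trials <- vector("list", n_all * ntr)
  k <- 0L
  for (p in seq_len(n_all)) {
    for (tr in seq_len(ntr)) {
      k <- k + 1L
      trials[[k]] <- simulate_trial(
        patterns[[orders[[p]][tr]]], draws[[p]],
        duration = config$duration_s, fs = config$fs,
        seed = trial_seed(config$seed, p, tr), with_gaze = with_gaze,
        participant_id = ids[p], sex = sexes[p], age = ages[p],
        trial_index = tr)
    }
  }
  manifest <- data.frame(
    participant_id = ids, sex = sexes, age = ages,
    hand_lag_ms = vapply(draws, `[[`, 0, "hand_lag_ms"),
    hand_noise_sd = vapply(draws, `[[`, 0, "hand_noise_sd"),
    hand_drift_sd = vapply(draws, `[[`, 0, "hand_drift_sd"),
    sp_gain = vapply(draws, `[[`, 0, "sp_gain"),
    eye_lag_ms = vapply(draws, `[[`, 0, "eye_lag_ms"),
    saccade_threshold_cm = vapply(draws, `[[`, 0, "saccade_threshold_cm"),
    onset_latency_ms = vapply(draws, `[[`, 0, "onset_latency_ms"),
    eye_noise_sd = vapply(draws, `[[`, 0, "eye_noise_sd"),
    stringsAsFactors = FALSE)
  list(trials = trials, manifest = manifest)
}
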