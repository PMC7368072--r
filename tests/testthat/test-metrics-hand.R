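test_that("mean Euclidean distance: identity, offsets, symmetry, errors", {
  s <- sample_trajectory(first_patterns()[[2]], 2, 500)
  a <- cbind(s$x, s$y)
  expect_equal(mean_euclidean_distance(a, a), 0)
  b <- cbind(a[, 1] + 3, a[, 2] + 4)
  expect_equal(mean_euclidean_distance(a, b), 5)
  expect_equal(mean_euclidean_distance(a, b), mean_euclidean_distance(b, a))
  expect_error(mean_euclidean_distance(a, b[-1, ]), "same length")
})

test_that("interleaved cross-correlation recovers constructed delays exactly", {
  s <- sample_trajectory(first_patterns()[[1]], 10, 1000)
  a <- cbind(s$x, s$y)
  expect_equal(interleaved_xcorr_lag(a, a, 1000, 500),
               list(lag_ms = 0, r = 1), tolerance = 1e-9)
  for (k in c(10, 25, 150)) {
    del <- a[pmax(1, seq_len(nrow(a)) - k), ]
    res <- interleaved_xcorr_lag(del[1001:10000, ], a[1001:10000, ], 1000, 500)
    expect_equal(res$lag_ms, k)        # positive: first argument trails
    expect_equal(res$r, 1, tolerance = 1e-6)
  }
  expect_error(interleaved_xcorr_lag(a * 0, a, 1000, 500), "constant")
  expect_error(interleaved_xcorr_lag(a, a, 1000, 6000), "half the duration")
})

test_that("fast lag estimator equals the brute-force interleaved oracle", {
  set.seed(71)
  for (i in 1:12) {
    n <- sample(80:400, 1)
    a <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
    b <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
    ml <- sample(c(20, 35), 1)
    f <- interleaved_xcorr_lag(a, b, 1000, ml)
    g <- bf_interleaved_lag(a, b, 1000, ml)
    expect_identical(f$lag_ms, g$lag_ms)
    expect_equal(f$r, g$r, tolerance = 1e-9)
  }
})

test_that("lag compensation removes a pure delay and never wraps", {
  s <- sample_trajectory(first_patterns()[[4]], 10, 1000)
  a <- cbind(s$x, s$y)
  cur <- a[pmax(1, seq_len(nrow(a)) - 60), ]
  expect_lt(lag_compensated_distance(cur, a, 60, 1000), 0.02)
  expect_equal(lag_compensated_distance(cur, a, 0, 1000),
               mean_euclidean_distance(cur, a))
  expect_error(lag_compensated_distance(cur, a, 7000, 1000), "50%")
})

test_that("residual distance at the estimated lag does not exceed raw distance", {
  pats <- first_patterns()
  worse <- 0
  for (i in 1:20) {
    cfg <- behavior_config(hand_lag_ms = 10 + 7 * i, onset_latency_ms = 0)
    tr <- simulate_trial(pats[[((i - 1) %% 5) + 1]], cfg, seed = 400 + i,
                         with_gaze = FALSE)
    xc <- interleaved_xcorr_lag(tr$cursor, tr$target, tr$fs, 500)
    raw <- mean_euclidean_distance(tr$cursor, tr$target)
    res <- lag_compensated_distance(tr$cursor, tr$target, xc$lag_ms, tr$fs)
    if (res > raw) worse <- worse + 1
  }
  expect_lte(worse, 1)   # >= 95% of seeds
})

test_that("tangential velocity is exact for uniform circular motion", {
  tt <- seq(0, 10, by = 1e-3)
  r <- 4; period <- 5
  xy <- cbind(r * cos(2 * pi * tt / period), r * sin(2 * pi * tt / period))
  tv <- tangential_velocity(xy, 1000)
  expect_equal(tv$mean, 2 * pi * r / period, tolerance = 1e-3)
  expect_lt(tv$sd, 0.05)
  still <- matrix(1, 100, 2)
  expect_equal(tangential_velocity(still, 1000)$mean, 0)
  s <- sample_trajectory(first_patterns()[[5]], 10, 1000)
  expect_equal(tangential_velocity(cbind(s$x, s$y), 1000)$mean, 16,
               tolerance = 0.05 * 16)
})

test_that("binned power spectrum localizes tones and conserves variance", {
  fs <- 1000; tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- 3 * sin(2 * pi * 0.22 * tt)
  psd <- power_spectrum_binned(x, fs)
  expect_equal(nrow(psd), 18)
  expect_equal(psd$freq, 0.11 * (1:18))
  # 0.22 Hz is not periodic in the 10-s window, so rectangular-window
  # leakage spreads a little energy; the tone's bin still dominates
  expect_equal(which.max(psd$power), 2)
  expect_gt(psd$power[2] * 0.11 / stats::var(x), 0.85)
  # Parseval for a band-limited mixture
  y <- 2 * sin(2 * pi * 0.3 * tt) + 1.2 * sin(2 * pi * 1.4 * tt + 1)
  py <- power_spectrum_binned(y, fs)
  expect_equal(sum(py$power) * 0.11, stats::var(y), tolerance = 0.05 * stats::var(y))
  expect_error(power_spectrum_binned(y[1:4000], fs), "9.1")
})

test_that("approximate entropy honors its contracts and the brute-force oracle", {
  expect_equal(approximate_entropy(rep(2, 150), 2, 0), 0)
  set.seed(9)
  tt <- seq(0, 4, length.out = 400)
  sine <- sin(2 * pi * tt)
  noise <- rnorm(400, sd = stats::sd(sine))
  expect_lt(approximate_entropy(sine, 2, 0.2 * stats::sd(sine)),
            approximate_entropy(noise, 2, 0.2 * stats::sd(noise)))
  x <- rnorm(200)
  r <- 0.2 * stats::sd(x)
  expect_equal(approximate_entropy(x, 2, r), bf_apen(x, 2, r),
               tolerance = 1e-10)
  # invariant under joint rescaling of signal and tolerance
  expect_equal(approximate_entropy(7 * x, 2, 7 * r),
               approximate_entropy(x, 2, r), tolerance = 1e-12)
  expect_error(approximate_entropy(x[1:3], 2), "too short")
})

test_that("submovement count matches analytic zero-crossing cases", {
  expect_equal(count_submovements(minjerk_reach(), 1000), 1L)
  # speed 1 + 0.5 sin(2 pi 0.2 t): four derivative zero crossings in 10 s
  tt <- seq(0, 10, by = 1e-3)
  xpos <- tt - 0.5 * cos(2 * pi * 0.2 * tt) / (2 * pi * 0.2)
  expect_equal(count_submovements(cbind(xpos, 0 * tt), 1000), 2L)
  # constant-speed circle: no tangential acceleration
  circ <- cbind(cos(2 * pi * 0.2 * tt), sin(2 * pi * 0.2 * tt))
  expect_equal(count_submovements(circ, 1000), 0L)
})

test_that("onset latency finds threshold crossings and handles absence", {
  fs <- 1000
  speed <- (seq_len(2000) - 1) / fs / 0.325 * 10  # linear ramp: 10 cm/s at 325 ms
  expect_equal(onset_latency(speed, fs, 10), 325, tolerance = 1.01)
  expect_true(is.na(onset_latency(rep(0, 100), fs)))
  cfg <- behavior_config(onset_latency_ms = 300, hand_noise_sd = 0,
                         hand_drift_sd = 0)
  errs <- sapply(1:5, function(i) {
    tr <- simulate_trial(first_patterns()[[i]], cfg, seed = i, with_gaze = FALSE)
    sp <- tangential_velocity(tr$cursor, tr$fs, cutoff_hz = 30)$speed
    onset_latency(sp, tr$fs) - 300
  })
  expect_lt(abs(mean(errs)), 10)
})

test_that("distance, lag, ApEn and submovements are translation invariant", {
  tr <- simulate_trial(first_patterns()[[2]], behavior_config(), seed = 12,
                       with_gaze = FALSE)
  a <- tr$cursor; b <- tr$target
  sh <- function(m) cbind(m[, 1] + 11, m[, 2] - 3)
  expect_equal(mean_euclidean_distance(sh(a), sh(b)),
               mean_euclidean_distance(a, b), tolerance = 1e-12)
  expect_equal(interleaved_xcorr_lag(sh(a), sh(b), 1000, 300)$lag_ms,
               interleaved_xcorr_lag(a, b, 1000, 300)$lag_ms)
  expect_equal(approximate_entropy(a[seq(1, 2000, 10), 1] + 5, 2, 0.3),
               approximate_entropy(a[seq(1, 2000, 10), 1], 2, 0.3),
               tolerance = 1e-12)
  expect_equal(count_submovements(sh(a), 1000), count_submovements(a, 1000))
})

test_that("analyze_hand_trial returns a fully populated metric row", {
  tr <- simulate_trial(first_patterns()[[3]], behavior_config(), seed = 31,
                       with_gaze = FALSE, participant_id = "M01", sex = "M")
  row <- analyze_hand_trial(tr)
  expect_s3_class(row, "data.frame")
  expect_equal(nrow(row), 1)
  expect_true(all(c("distance", "lag_ms", "xcorr_peak_r", "residual_distance",
                    "mean_tv", "sd_tv", "apen_x", "apen_y", "n_submovements",
                    "onset_latency_ms", "psd_x_01", "psd_x_18", "psd_y_18")
                  %in% names(row)))
  expect_gt(row$xcorr_peak_r, 0.55)   # tracking correlations are always high
  expect_gte(row$distance, row$residual_distance)
  # noise-free zero-lag trial: distance ~ 0 (smoothing distortion only), lag 0
  cfg0 <- behavior_config(hand_lag_ms = 0, hand_noise_sd = 0,
                          hand_drift_sd = 0, hand_cutoff_hz = Inf,
                          onset_latency_ms = 0)
  tr0 <- simulate_trial(first_patterns()[[1]], cfg0, seed = 1, with_gaze = FALSE)
  row0 <- analyze_hand_trial(tr0)
  expect_lt(row0$distance, 1e-9)
  expect_equal(row0$lag_ms, 0)
})

test_that("hand lag recovery and the sex contrast in raw distance", {
  pats <- first_patterns()
  hp <- hand_params(start_trim_s = 2)
  lags <- dists_f <- dists_m <- numeric(20)
  for (i in 1:20) {
    p <- pats[[((i - 1) %% 5) + 1]]
    trm <- simulate_trial(p, behavior_config(), seed = 900 + i, with_gaze = FALSE)
    trf <- simulate_trial(p, behavior_config(hand_lag_ms = 71), seed = 950 + i,
                          with_gaze = FALSE)
    rm_ <- analyze_hand_trial(trm, hp)
    rf <- analyze_hand_trial(trf, hp)
    lags[i] <- rm_$lag_ms
    dists_m[i] <- rm_$distance; dists_f[i] <- rf$distance
  }
  expect_lt(abs(mean(lags) - 49), 2)
  expect_gt(mean(dists_f), mean(dists_m))
})
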