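# Independent reference implementations used as oracles, plus small fixture
# builders. These deliberately use naive, direct formulations (loops,
# explicit means) so they share no code path with the package.

# Brute-force interleaved cross-correlation lag: builds the interleaved
# sequences explicitly and calls cor() at every whole-sample shift.
bf_interleaved_lag <- function(a, b, fs, max_lag_ms) {
  n <- nrow(a)
  K <- round(max_lag_ms / 1000 * fs)
  inter <- function(m) as.vector(t(m))
  best_r <- -Inf; best_k <- NA_integer_
  for (k in -K:K) {
    if (k >= 0) {
      ao <- a[(1 + k):n, , drop = FALSE]; bo <- b[1:(n - k), , drop = FALSE]
    } else {
      ao <- a[1:(n + k), , drop = FALSE]; bo <- b[(1 - k):n, , drop = FALSE]
    }
    r <- stats::cor(inter(ao), inter(bo))
    if (r > best_r || (r == best_r && abs(k) < abs(best_k))) {
      best_r <- r; best_k <- k
    }
  }
  list(lag_ms = best_k * 1000 / fs, r = best_r)
}

# Brute-force approximate entropy: explicit double loop over template pairs
# with Chebyshev distance, self-matches included.
bf_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1L
    counts <- numeric(nm)
    for (i in seq_len(nm)) {
      c_i <- 0L
      for (j in seq_len(nm)) {
        d <- 0
        for (l in 0:(mm - 1L)) d <- max(d, abs(x[i + l] - x[j + l]))
        if (d <= r) c_i <- c_i + 1L
      }
      counts[i] <- c_i / nm
    }
    mean(log(counts))
  }
  phi(m) - phi(m + 1L)
}

# Split-plot (mixed-design) sums of squares from explicit cell means.
bf_split_plot <- function(values, between) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  g <- factor(between); m <- mean(values)
  subj_means <- rowMeans(values)
  grp_means <- tapply(subj_means, g, mean)
  lev_means <- colMeans(values)
  ss_A <- k * sum(table(g) * (grp_means - m)^2)
  ss_subj <- k * sum((subj_means - grp_means[as.character(g)])^2)
  ss_W <- n * sum((lev_means - m)^2)
  ss_int <- 0
  for (gi in levels(g)) for (l in seq_len(k)) {
    cm <- mean(values[g == gi, l])
    ss_int <- ss_int + sum(g == gi) *
      (cm - grp_means[gi] - lev_means[l] + m)^2
  }
  ss_tot <- sum((values - m)^2)
  c(between = unname(ss_A), subjects = unname(ss_subj),
    within = unname(ss_W), interaction = unname(ss_int),
    error = unname(ss_tot - ss_A - ss_subj - ss_W - ss_int),
    total = unname(ss_tot))
}

# Minimum-jerk point-to-point displacement profile on [0, 1].
minjerk_profile <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}

# A single minimum-jerk point-to-point reach as an xy series.
minjerk_reach <- function(from = c(0, 0), to = c(10, 0), duration = 1,
                          fs = 1000) {
  tt <- seq(0, duration, by = 1 / fs)
  p <- minjerk_profile(tt / duration)
  cbind(from[1] + p * (to[1] - from[1]), from[2] + p * (to[2] - from[2]))
}

# Pursuit-only gaze fixture: gain-scaled integral of the target velocity
# (no saccades), built by direct numerical integration.
pursuit_only_gaze <- function(target, fs, gain = 0.8) {
  v <- apply(target, 2, function(cc) {
    n <- length(cc)
    d <- numeric(n)
    d[2:(n - 1)] <- (cc[3:n] - cc[1:(n - 2)]) * fs / 2
    d[1] <- (cc[2] - cc[1]) * fs; d[n] <- (cc[n] - cc[n - 1]) * fs
    d
  })
  disp <- rbind(c(0, 0), (v[-1, ] + v[-nrow(v), ]) / 2 / fs)
  sweep(gain * apply(disp, 2, cumsum), 2, target[1, ], `+`)
}

first_patterns <- function() load_pattern_table()
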