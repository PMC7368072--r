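test_that("participant aggregation averages trials and rejects duplicates", {
  tm <- data.frame(participant_id = rep(c("a", "b"), each = 10),
                   sex = rep(c("F", "M"), each = 10),
                   trial_index = rep(1:10, 2),
                   distance = c(rep(2.5, 10), 1:10))
  sm <- aggregate_participants(tm)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$distance[sm$participant_id == "a"], 2.5)
  expect_equal(sm$distance[sm$participant_id == "b"], 5.5)
  tm2 <- rbind(tm, tm[1, ])
  expect_error(aggregate_participants(tm2), "duplicate")
})

test_that("pooled t-test agrees with the reference implementation", {
  set.seed(42)
  for (i in 1:100) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    mine <- t_test_independent(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("t-test degenerate and summary-statistic behavior", {
  x <- c(1, 2, 3, 4)
  r <- t_test_independent(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(t_test_summary(1, 0, 5, 1, 0, 5), "pooled variance")
  expect_error(t_test_independent(1, c(1, 2)), "n >= 2")
  # printed worked example: distance 1.87 +- 0.42 vs 1.62 +- 0.30, n = 25/25
  w <- t_test_summary(1.87, 0.42, 25, 1.62, 0.30, 25)
  expect_equal(w$df, 48)
  expect_equal(w$t, 2.43, tolerance = 0.011)
  expect_lt(w$p, 0.05)
})

test_that("Cohen's d matches printed values and is scale invariant", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 1, 3)), 0)
  expect_equal(cohens_d_summary(1.87, 0.42, 25, 1.62, 0.30, 25), 0.69,
               tolerance = 0.011)
  expect_equal(cohens_d_summary(71, 25, 25, 49, 21, 25), 0.953,
               tolerance = 0.005)
  set.seed(3)
  a <- rnorm(20, 1); b <- rnorm(20)
  expect_equal(cohens_d(10 * a, 10 * b), cohens_d(a, b), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("mixed ANOVA reproduces the hand-computed split-plot table", {
  vals <- matrix(c(1, 2, 2, 4, 3, 5, 4, 7), 4, 2, byrow = TRUE)
  tab <- mixed_anova_2way(vals, c("A", "A", "B", "B"))
  get <- function(src, col) tab[tab$source == src, col]
  expect_equal(get("between", "ss"), 12.5)
  expect_equal(get("subjects_within_groups", "ss"), 4.5)
  expect_equal(get("within", "ss"), 8)
  expect_equal(get("interaction", "ss"), 0.5)
  expect_equal(get("within_error", "ss"), 0.5)
  expect_equal(get("between", "F"), 5.5556, tolerance = 1e-4)
  expect_equal(get("within", "F"), 32)
  expect_equal(get("interaction", "F"), 2)
  expect_equal(get("interaction", "p"), 0.29289, tolerance = 1e-4)
})

test_that("mixed ANOVA decomposition matches the SS oracle on random designs", {
  set.seed(8)
  for (i in 1:10) {
    n_per <- sample(3:6, 1); k <- sample(2:5, 1)
    vals <- matrix(rnorm(2 * n_per * k), 2 * n_per, k)
    grp <- rep(c("F", "M"), each = n_per)
    tab <- mixed_anova_2way(vals, grp)
    ora <- bf_split_plot(vals, grp)
    expect_equal(sum(tab$ss), unname(ora["total"]), tolerance = 1e-8)
    expect_equal(tab$ss[tab$source == "between"], unname(ora["between"]),
                 tolerance = 1e-8)
    expect_equal(tab$ss[tab$source == "interaction"],
                 unname(ora["interaction"]), tolerance = 1e-8)
    expect_equal(sum(tab$df), length(vals) - 1)
  }
  expect_error(mixed_anova_2way(matrix(c(1, NA, 2, 3), 2, 2), c("A", "B")),
               "complete")
})

test_that("one within level reduces the between F to the squared pooled t", {
  set.seed(5)
  a <- rnorm(8, 1); b <- rnorm(9)
  tab <- mixed_anova_2way(matrix(c(a, b), ncol = 1), rep(c("A", "B"), c(8, 9)))
  tt <- t_test_independent(a, b)
  expect_equal(tab$F[tab$source == "between"], tt$t^2, tolerance = 1e-8)
})

test_that("eye-hand correlation is computed per group", {
  sm <- data.frame(participant_id = sprintf("p%02d", 1:20),
                   sex = rep(c("F", "M"), each = 10),
                   distance = NA_real_, eye_target_distance = NA_real_,
                   lag_ms = NA_real_, eye_target_lag_ms = NA_real_)
  set.seed(10)
  sm$eye_target_distance <- rnorm(20, 1.4, 0.3)
  sm$distance <- 1.1 * sm$eye_target_distance + rep(c(0.3, 0), each = 10)
  sm$eye_target_lag_ms <- rnorm(20, 60, 10)
  sm$lag_ms <- sm$eye_target_lag_ms + rep(c(15, 0), each = 10) + rnorm(20, 0, 2)
  ec <- eye_hand_correlation(sm, "distance", "eye_target_distance")
  expect_equal(ec$sex, c("F", "M"))
  expect_true(all(ec$r > 0.9))
  perf <- sm; perf$distance <- 2 * perf$eye_target_distance
  expect_equal(eye_hand_correlation(perf)$r, c(1, 1), tolerance = 1e-12)
  cst <- sm; cst$distance <- 1
  expect_error(eye_hand_correlation(cst), "constant")
  expect_error(eye_hand_correlation(sm[c(1, 2, 11, 12), ]), "n >= 3")
})

test_that("shared participant-level noise yields within-group eye-hand coupling", {
  cc <- cohort_config(n_female = 12, n_male = 12, trials_per_participant = 5,
                      fs = 250, eye_hand_rho = 0.8, seed = 31)
  coh <- simulate_cohort(cc)
  gp <- gaze_params(start_trim_s = 2, max_lag_ms = 300)
  hp <- hand_params(start_trim_s = 2, max_lag_ms = 300)
  rows <- lapply(coh$trials, function(tr) {
    h <- data.frame(participant_id = tr$participant_id, sex = tr$sex,
                    trial_index = tr$trial_index)
    keep <- seq(2 * tr$fs + 1, length(tr$time))
    h$distance <- mean_euclidean_distance(tr$cursor[keep, ], tr$target[keep, ])
    h$lag_ms <- interleaved_xcorr_lag(tr$cursor[keep, ], tr$target[keep, ],
                                      tr$fs, 300)$lag_ms
    g <- analyze_gaze_trial(tr, gp)
    h$eye_target_distance <- g$eye_target_distance
    h$eye_target_lag_ms <- g$eye_target_lag_ms
    h
  })
  sm <- aggregate_participants(do.call(rbind, rows))
  ec <- eye_hand_correlation(sm, "lag_ms", "eye_target_lag_ms")
  expect_true(all(ec$r > 0))
  # the female group's hand lag sits above the male group's at matched eye lag
  expect_gt(mean(sm$lag_ms[sm$sex == "F"]) - mean(sm$lag_ms[sm$sex == "M"]), 5)
})

test_that("greedy age matching trims the right tails deterministically", {
  meta <- data.frame(participant_id = sprintf("p%02d", 1:20),
                     sex = rep(c("F", "M"), each = 10),
                     age = c(21:30, 25:34))
  res <- age_match(meta, tol = 0.5)
  expect_true(res$converged)
  gap <- abs(diff(tapply(res$retained$age, res$retained$sex, mean)))
  expect_lt(gap, 0.5)
  # removals alternate oldest-male / youngest-female
  expect_true(all(res$removed$sex %in% c("F", "M")))
  expect_true(all(res$removed$age[res$removed$sex == "M"] >= 31))
  expect_true(all(res$removed$age[res$removed$sex == "F"] <= 24))
  # already matched: nothing removed
  ok <- data.frame(participant_id = sprintf("q%02d", 1:10),
                   sex = rep(c("F", "M"), 5), age = rep(25, 10))
  expect_equal(nrow(age_match(ok)$removed), 0)
  # age ties broken by participant id order
  tie <- data.frame(participant_id = c("a", "b", "c", "d"),
                    sex = c("M", "M", "F", "F"), age = c(30, 30, 20, 20))
  r2 <- suppressWarnings(age_match(tie, tol = 0.5, max_remove = 2))
  expect_equal(r2$removed$participant_id[1], "a")
  expect_warning(age_match(tie, tol = 0.1, max_remove = 1), "cap")
})

test_that("pooled t matches the permutation-test limit on larger samples", {
  set.seed(17)
  a <- rnorm(60, 0.3); b <- rnorm(60)
  tt <- t_test_independent(a, b)
  pool <- c(a, b)
  perm_t <- replicate(4000, {
    idx <- sample(120, 60)
    t_test_independent(pool[idx], pool[-idx])$t
  })
  p_perm <- mean(abs(perm_t) >= abs(tt$t))
  expect_lt(abs(p_perm - tt$p), 0.03)
})
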