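# Participant-level aggregation and group statistics: pooled t-tests,
# Cohen's d, mixed-design (split-plot) ANOVA, per-group eye-hand
# correlations, and age matching.

#' Average trial metrics within participants
#'
#' Each dependent variable is averaged across a participant's trials, giving
#' one row per participant; group statistics are then computed on these
#' participant means.
#'
#' @param trial_metrics data.frame of per-trial metric rows with
#'   `participant_id`, `sex`, `trial_index` and numeric metric columns.
#' @return A data.frame with one row per participant (metric columns
#'   averaged over that participant's available trials).
#' @export
aggregate_participants <- function(trial_metrics) {
  need <- c("participant_id", "sex", "trial_index")
  if (!all(need %in% names(trial_metrics)))
    stop("trial metrics need columns: ", paste(need, collapse = ", "))
  key <- paste(trial_metrics$participant_id, trial_metrics$trial_index)
  if (anyDuplicated(key))
    stop("duplicate (participant, trial) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  num <- names(trial_metrics)[vapply(trial_metrics, is.numeric, TRUE)]
  num <- setdiff(num, c("trial_index", "pattern_id"))
  agg <- stats::aggregate(trial_metrics[num],
                          by = list(participant_id = trial_metrics$participant_id),
                          FUN = mean)
  sex <- trial_metrics$sex[match(agg$participant_id, trial_metrics$participant_id)]
  cbind(agg[1], sex = sex, agg[-1], stringsAsFactors = FALSE)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's t with the pooled-variance estimate and `n1 + n2 - 2` degrees
#' of freedom, two-sided, plus Cohen's d. Entry from summary statistics so
#' printed group means/SDs can be checked directly.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param metric optional metric name carried in the result.
#' @param label1,label2 group labels.
#' @return A `group_result` data.frame row: group means/SDs/ns, `t`, `df`,
#'   two-sided `p`, and `d`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           metric = NA_character_,
                           label1 = "group1", label2 = "group2") {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance: t undefined")
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  res <- data.frame(metric = metric, label1 = label1, label2 = label2,
                    mean1 = mean1, sd1 = sd1, n1 = n1,
                    mean2 = mean2, sd2 = sd2, n2 = n2,
                    t = tval, df = df,
                    p = 2 * stats::pt(-abs(tval), df),
                    d = (mean1 - mean2) / sqrt(sp2),
                    stringsAsFactors = FALSE)
  class(res) <- c("group_result", "data.frame")
  res
}

#' Pooled two-sample t-test on raw values
#'
#' @param group_a,group_b numeric vectors of participant-level values.
#' @inheritParams t_test_summary
#' @return See [t_test_summary()].
#' @export
t_test_independent <- function(group_a, group_b, metric = NA_character_,
                               label1 = "group1", label2 = "group2") {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  t_test_summary(mean(group_a), stats::sd(group_a), length(group_a),
                 mean(group_b), stats::sd(group_b), length(group_b),
                 metric = metric, label1 = label1, label2 = label2)
}

#' Cohen's d from summary statistics
#'
#' Mean difference over the pooled SD; the pooled SD uses `(n-1)`-weighted
#' variances, reducing to `sqrt((s1^2 + s2^2)/2)` at equal group sizes.
#'
#' @inheritParams t_test_summary
#' @return Cohen's d (signed; positive when group 1 exceeds group 2).
#' @export
cohens_d_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled SD: d undefined")
  (mean1 - mean2) / sqrt(sp2)
}

#' Cohen's d from raw values
#'
#' @param group_a,group_b numeric vectors.
#' @return Cohen's d.
#' @export
cohens_d <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  cohens_d_summary(mean(group_a), stats::sd(group_a), length(group_a),
                   mean(group_b), stats::sd(group_b), length(group_b))
}

#' Mixed-design (split-plot) two-way ANOVA
#'
#' Classical mixed-model decomposition for one between-subject factor (e.g.
#' sex) crossed with one within-subject factor (e.g. frequency bin or trial
#' index): the between effect is tested against the subject-within-group
#' stratum, the within effect and the interaction against the within-subject
#' error. Requires a complete balanced design (every participant measured at
#' every within level); missing cells are rejected rather than imputed.
#'
#' @param values numeric matrix, participants x within-factor levels (or a
#'   data.frame of the same shape).
#' @param between factor/character vector of group labels, one per
#'   participant.
#' @return An `anova_table` data.frame with one row per source (`between`,
#'   `subjects_within_groups`, `within`, `interaction`, `within_error`):
#'   sums of squares, df, F and p where defined.
#' @export
mixed_anova_2way <- function(values, between) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("missing cells: design must be complete")
  n <- nrow(values); k <- ncol(values)
  if (length(between) != n) stop("'between' must have one label per row")
  between <- factor(between)
  if (nlevels(between) < 2) stop("need at least two groups")
  long <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    grp = rep(between, times = k),
    w = factor(rep(seq_len(k), each = n)))
  grab <- function(tab, i) {
    c(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
      F = if ("F value" %in% names(tab)) tab[i, "F value"] else NA_real_,
      p = if ("Pr(>F)" %in% names(tab)) tab[i, "Pr(>F)"] else NA_real_)
  }
  if (k == 1L) {
    # degenerate within factor: only the between stratum exists, and the
    # between F equals the squared pooled t
    s1 <- summary(stats::aov(y ~ grp, data = long))[[1]]
    out <- rbind(between = grab(s1, 1), subjects_within_groups = grab(s1, 2))
  } else {
    s <- summary(stats::aov(y ~ grp * w + Error(subject), data = long))
    bet <- as.data.frame(s[["Error: subject"]][[1]])
    wit <- as.data.frame(s[["Error: Within"]][[1]])
    out <- rbind(between = grab(bet, 1),
                 subjects_within_groups = grab(bet, 2),
                 within = grab(wit, 1),
                 interaction = grab(wit, 2),
                 within_error = grab(wit, 3))
  }
  out <- data.frame(source = rownames(out), out, row.names = NULL)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Per-group correlation between an eye metric and a hand metric
#'
#' Pearson correlation between two participant-level metrics, computed
#' separately within each group. Used to show that eye and hand tracking
#' accuracy covary across individuals within each sex.
#'
#' @param summaries participant summary data.frame (see
#'   [aggregate_participants()]) with a `sex` column.
#' @param hand_metric,eye_metric column names to correlate.
#' @return A data.frame with one row per group: `sex`, `n`, `r`, `p`.
#' @export
eye_hand_correlation <- function(summaries, hand_metric = "distance",
                                 eye_metric = "eye_target_distance") {
  for (m in c(hand_metric, eye_metric))
    if (!m %in% names(summaries)) stop("missing metric column: ", m)
  groups <- sort(unique(summaries$sex))
  out <- lapply(groups, function(g) {
    d <- summaries[summaries$sex == g, ]
    x <- d[[eye_metric]]; y <- d[[hand_metric]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need n >= 3 per group")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("constant metric in group ", g, ": correlation undefined")
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(sex = g, n = length(x), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Match group ages by greedy trimming
#'
#' Removes the oldest remaining participant of the older group and the
#' youngest remaining participant of the younger group, in alternation,
#' until the group mean ages differ by less than `tol` years or the removal
#' cap is reached. Deterministic; age ties are broken by participant id
#' order.
#'
#' @param meta data.frame with `participant_id`, `sex` and `age` (years).
#' @param tol tolerated difference in group mean age, years.
#' @param max_remove cap on total removals.
#' @return A list: `retained` (subset of `meta`), `removed` (removal log
#'   with the running age gap), `converged` (logical).
#' @export
age_match <- function(meta, tol = 0.5, max_remove = 20) {
  if (!all(c("participant_id", "sex", "age") %in% names(meta)))
    stop("'meta' needs participant_id, sex and age columns")
  if (any(is.na(meta$age))) stop("ages must be present for all participants")
  meta <- meta[order(meta$participant_id), ]
  removed <- meta[0, ]
  gap_log <- numeric(0)
  gap <- function(d) {
    means <- tapply(d$age, d$sex, mean)
    if (length(means) < 2) return(0)
    means[[which.max(means)]] - means[[which.min(means)]]
  }
  repeat {
    g <- gap(meta)
    if (g < tol || nrow(removed) >= max_remove) break
    means <- tapply(meta$age, meta$sex, mean)
    older <- names(means)[which.max(means)]
    younger <- names(means)[which.min(means)]
    # alternate: drop oldest of the older group, then youngest of the other
    for (side in list(c(older, "max"), c(younger, "min"))) {
      if (gap(meta) < tol || nrow(removed) >= max_remove) break
      d <- meta[meta$sex == side[1], ]
      idx <- if (side[2] == "max") which(d$age == max(d$age))[1] else
        which(d$age == min(d$age))[1]
      drop_id <- d$participant_id[idx]
      removed <- rbind(removed, meta[meta$participant_id == drop_id, ])
      gap_log <- c(gap_log, NA_real_)
      meta <- meta[meta$participant_id != drop_id, ]
      gap_log[length(gap_log)] <- gap(meta)
    }
  }
  conv <- gap(meta) < tol
  if (!conv)
    warning(sprintf("age matching stopped at the removal cap with a %.2f-y gap",
                    gap(meta)))
  if (nrow(removed)) removed$gap_after <- gap_log
  list(retained = meta, removed = removed, converged = conv)
}

#' @export
print.group_result <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s: %s = %.3g ± %.3g vs. %s = %.3g ± %.3g; t(%d) = %.2f; p = %.3g; d = %.2f\n",
                if (is.na(x$metric[i])) "metric" else x$metric[i],
                x$label1[i], x$mean1[i], x$sd1[i],
                x$label2[i], x$mean2[i], x$sd2[i],
                x$df[i], x$t[i], x$p[i], x$d[i]))
  }
  invisible(x)
}
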