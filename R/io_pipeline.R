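# Trial file I/O (tidy CSV), run configuration round-tripping, and the
# pipeline entry points: simulate a cohort to disk, analyze a directory of
# trials, run the group statistics, and produce an end-to-end report.

.vt_version <- function()
  as.character(utils::packageVersion("visuotrack"))

#' Write a trial to a tidy CSV file
#'
#' Metadata travel as `# key: value` comment lines above the header; samples
#' are long-format rows (`time_s, target_x_cm, target_y_cm, cursor_x_cm,
#' cursor_y_cm[, gaze_x_cm, gaze_y_cm]`). Values are written with 12
#' significant digits, so a write/read round trip is lossless to well below
#' 1e-9 cm.
#'
#' @param trial a `vt_trial`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "vt_trial"))
  has_gaze <- !is.null(trial$gaze)
  meta <- c(sprintf("# visuotrack %s", .vt_version()),
            sprintf("# participant_id: %s", trial$participant_id),
            sprintf("# sex: %s", trial$sex),
            sprintf("# age: %s", format(trial$age, digits = 10)),
            sprintf("# trial_index: %d", trial$trial_index),
            sprintf("# pattern_id: %d", trial$pattern_id),
            sprintf("# fs_hz: %s", format(trial$fs, digits = 12)),
            sprintf("# has_gaze: %s", has_gaze))
  df <- data.frame(time_s = trial$time,
                   target_x_cm = trial$target[, 1],
                   target_y_cm = trial$target[, 2],
                   cursor_x_cm = trial$cursor[, 1],
                   cursor_y_cm = trial$cursor[, 2])
  if (has_gaze) {
    df$gaze_x_cm <- trial$gaze[, 1]
    df$gaze_y_cm <- trial$gaze[, 2]
  }
  if (!is.null(trial$extra)) df <- cbind(df, trial$extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(v) sprintf("%.12g", v)),
                           sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a trial from a tidy CSV file
#'
#' @param path file written by [write_trial()] (or any CSV with the same
#'   columns; `# key: value` comment headers are optional).
#' @return A `vt_trial`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such trial file: ", path)
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "target_x_cm", "target_y_cm", "cursor_x_cm", "cursor_y_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  gaze_cols <- c("gaze_x_cm", "gaze_y_cm")
  n_gaze <- sum(gaze_cols %in% names(df))
  if (n_gaze == 1L)
    stop(path, ": gaze columns must be all present or all absent")
  if (nrow(df) < 2L) stop(path, ": trial has fewer than 2 samples")
  if (any(!is.finite(as.matrix(df[need]))))
    stop(path, ": non-finite sample values (missing samples mid-trial?)")
  dt <- diff(df$time_s)
  fs <- if (!is.null(meta$fs_hz)) as.numeric(meta$fs_hz) else 1 / stats::median(dt)
  if (any(abs(dt - 1 / fs) > 1e-9))
    stop(sprintf("%s: time stamps inconsistent with fs = %g Hz (first offence at data row %d)",
                 path, fs, which(abs(dt - 1 / fs) > 1e-9)[1] + 1L))
  structure(list(
    participant_id = if (!is.null(meta$participant_id)) meta$participant_id else "unknown",
    sex = if (!is.null(meta$sex)) meta$sex else NA_character_,
    age = if (is.null(meta$age) || meta$age %in% c("NA", "NaN")) NA_real_ else
      as.numeric(meta$age),
    trial_index = if (!is.null(meta$trial_index)) as.integer(meta$trial_index) else 1L,
    pattern_id = if (!is.null(meta$pattern_id)) as.integer(meta$pattern_id) else NA_integer_,
    fs = fs, time = df$time_s,
    target = cbind(x = df$target_x_cm, y = df$target_y_cm),
    cursor = cbind(x = df$cursor_x_cm, y = df$cursor_y_cm),
    gaze = if (n_gaze == 2L) cbind(x = df$gaze_x_cm, y = df$gaze_y_cm) else NULL,
    extra = {  # unknown extra columns are preserved across a round trip
      known <- c(need, gaze_cols)
      if (length(setdiff(names(df), known)))
        df[setdiff(names(df), known)] else NULL
    }),
    class = "vt_trial")
}

#' Write / read a run configuration
#'
#' The full pipeline configuration (cohort simulation parameters, hand and
#' gaze analysis parameters, master seed) round-trips losslessly through a
#' human-editable YAML file.
#'
#' @param config a list with elements `cohort` ([cohort_config()]), `hand`
#'   ([hand_params()]), `gaze` ([gaze_params()]).
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the reconstructed configuration list.
#' @export
write_run_config <- function(config, path) {
  x <- list(cohort = unclass(config$cohort), hand = config$hand,
            gaze = config$gaze)
  x$cohort$female <- unclass(x$cohort$female)
  x$cohort$male <- unclass(x$cohort$male)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  ch <- x$cohort
  ch$female <- do.call(behavior_config, ch$female)
  ch$male <- do.call(behavior_config, ch$male)
  list(cohort = do.call(cohort_config, ch),
       hand = do.call(hand_params, x$hand),
       gaze = do.call(gaze_params, x$gaze))
}

.default_run_config <- function(seed = 1)
  list(cohort = cohort_config(seed = seed), hand = hand_params(),
       gaze = gaze_params())

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

.provenance <- function(config, seed)
  sprintf("# visuotrack %s; seed %s; config %s", .vt_version(), seed,
          .config_hash(config))

#' Simulate a cohort and write it to a directory of trial files
#'
#' Writes one CSV per trial plus `manifest.csv` (participant metadata and
#' the drawn behavioral parameters). All outputs carry a provenance comment
#' (package version, seed, config hash).
#'
#' @param config a run configuration (see [write_run_config()]); defaults
#'   to the standard cohort.
#' @param out_dir output directory (created if needed).
#' @param with_gaze simulate and write the gaze channel?
#' @return Invisibly, a list with `trial_files` and `manifest_file`.
#' @export
run_simulate <- function(config = .default_run_config(), out_dir,
                         with_gaze = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coh <- simulate_cohort(config$cohort, with_gaze = with_gaze)
  files <- character(length(coh$trials))
  for (i in seq_along(coh$trials)) {
    tr <- coh$trials[[i]]
    files[i] <- file.path(out_dir, sprintf("trial_%s_%02d.csv",
                                           tr$participant_id, tr$trial_index))
    write_trial(tr, files[i])
  }
  mf <- file.path(out_dir, "manifest.csv")
  con <- file(mf, "w")
  writeLines(.provenance(config, config$cohort$seed), con)
  utils::write.csv(coh$manifest, con, row.names = FALSE)
  close(con)
  message(sprintf("simulate: wrote %d trials + manifest to %s",
                  length(files), out_dir))
  invisible(list(trial_files = files, manifest_file = mf))
}

#' Analyze a directory of trial files into per-trial metric rows
#'
#' @param in_dir directory of trial CSVs (as written by [run_simulate()]
#'   or [write_trial()]).
#' @param out_csv output metrics CSV (one tidy row per trial).
#' @param hand,gaze analysis parameters.
#' @param no_gaze skip gaze metrics even when the channel is present.
#' @param config run configuration used only for output provenance.
#' @return The metrics data.frame, invisibly.
#' @export
run_analyze <- function(in_dir, out_csv, hand = hand_params(),
                        gaze = gaze_params(), no_gaze = FALSE,
                        config = .default_run_config()) {
  files <- sort(list.files(in_dir, pattern = "^trial_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files))
    stop("no trial files found in ", in_dir)
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    tr <- read_trial(files[i])
    row <- analyze_hand_trial(tr, hand)
    if (!no_gaze && !is.null(tr$gaze)) {
      g <- analyze_gaze_trial(tr, gaze)
      row <- cbind(row, g[setdiff(names(g), names(row))])
    }
    rows[[i]] <- row
  }
  metrics <- do.call(rbind, rows)
  con <- file(out_csv, "w")
  writeLines(.provenance(config, config$cohort$seed), con)
  utils::write.csv(metrics, con, row.names = FALSE)
  close(con)
  message(sprintf("analyze: %d trials -> %s", nrow(metrics), out_csv))
  invisible(metrics)
}

.report_metrics <- c(
  distance = "cursor-target distance (cm)",
  lag_ms = "cursor-target lag (ms)",
  residual_distance = "residual distance after lag compensation (cm)",
  mean_tv = "mean cursor tangential velocity (cm/s)",
  sd_tv = "SD of cursor tangential velocity (cm/s)",
  apen_x = "approximate entropy, horizontal",
  apen_y = "approximate entropy, vertical",
  n_submovements = "submovement count",
  onset_latency_ms = "cursor onset latency (ms)",
  eye_target_distance = "eye-target distance (cm)",
  eye_target_lag_ms = "eye-target lag (ms)",
  saccade_rate = "saccadic rate (1/s)",
  sp_gain = "smooth pursuit gain")

#' Group statistics over a per-trial metrics table
#'
#' Averages metrics within participants, then compares the female and male
#' groups with pooled t-tests (plus Cohen's d) for every metric present,
#' runs the SEX x FREQUENCY mixed ANOVA on the binned cursor power spectra
#' and the SEX x TRIAL mixed ANOVA on the per-trial lag, and writes a
#' machine-readable CSV plus a human-readable text report.
#'
#' @param metrics per-trial metrics (data.frame or path to the CSV from
#'   [run_analyze()]).
#' @param out_dir output directory.
#' @param config run configuration used for provenance.
#' @return Invisibly, a list with `summaries` (participant means),
#'   `group_results`, `anova` (list of `anova_table`), and the per-group
#'   eye-hand correlations when gaze metrics are present.
#' @export
run_stats <- function(metrics, out_dir, config = .default_run_config()) {
  if (is.character(metrics)) metrics <- utils::read.csv(metrics, comment.char = "#")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- aggregate_participants(metrics)
  if (!all(c("F", "M") %in% summ$sex))
    stop("need both F and M participants for group statistics")
  res <- list()
  for (m in intersect(names(.report_metrics), names(summ))) {
    f <- summ[[m]][summ$sex == "F"]; ml <- summ[[m]][summ$sex == "M"]
    if (all(is.na(f)) || all(is.na(ml))) next
    res[[m]] <- t_test_independent(f, ml, metric = m,
                                   label1 = "F", label2 = "M")
  }
  group_results <- do.call(rbind, res)

  anovas <- list()
  for (ax in c("x", "y")) {
    cols <- sprintf("psd_%s_%02d", ax, 1:18)
    if (all(cols %in% names(summ)))
      anovas[[paste0("sex_by_frequency_", ax)]] <-
        mixed_anova_2way(as.matrix(summ[cols]), summ$sex)
  }
  if ("lag_ms" %in% names(metrics)) {
    wide <- stats::reshape(
      metrics[c("participant_id", "trial_index", "lag_ms")],
      idvar = "participant_id", timevar = "trial_index", direction = "wide")
    sex <- metrics$sex[match(wide$participant_id, metrics$participant_id)]
    if (!anyNA(wide[-1]))
      anovas$sex_by_trial_lag <- mixed_anova_2way(as.matrix(wide[-1]), sex)
  }
  corr <- NULL
  if (all(c("eye_target_distance", "distance") %in% names(summ)))
    corr <- rbind(
      cbind(pair = "distance", eye_hand_correlation(
        summ, "distance", "eye_target_distance")),
      cbind(pair = "lag", eye_hand_correlation(
        summ, "lag_ms", "eye_target_lag_ms")))

  prov <- .provenance(config, config$cohort$seed)
  con <- file(file.path(out_dir, "group_results.csv"), "w")
  writeLines(prov, con)
  utils::write.csv(group_results, con, row.names = FALSE)
  close(con)
  rep_lines <- c(prov, "Group comparison (female vs. male participant means)",
                 "")
  for (m in names(res)) {
    x <- res[[m]]
    rep_lines <- c(rep_lines, sprintf(
      "%s: F = %.3g ± %.3g vs. M = %.3g ± %.3g; t(%d) = %.2f; p = %.3g; d = %.2f",
      .report_metrics[[m]], x$mean1, x$sd1, x$mean2, x$sd2, x$df, x$t, x$p, x$d))
  }
  for (nm in names(anovas)) {
    a <- anovas[[nm]]
    rep_lines <- c(rep_lines, "", paste0("Mixed ANOVA: ", nm))
    rep_lines <- c(rep_lines, utils::capture.output(print.data.frame(a)))
  }
  if (!is.null(corr)) {
    rep_lines <- c(rep_lines, "", "Eye-hand correlations by group:")
    rep_lines <- c(rep_lines, utils::capture.output(print.data.frame(corr)))
  }
  writeLines(rep_lines, file.path(out_dir, "report.txt"))
  message("stats: wrote group_results.csv and report.txt to ", out_dir)
  invisible(list(summaries = summ, group_results = group_results,
                 anova = anovas, eye_hand = corr))
}

#' End-to-end replication run
#'
#' Simulates a cohort, analyzes every trial, runs the group statistics and
#' writes a replication summary of the headline trio: raw cursor-target
#' distance, cursor-target lag, and lag-compensated residual distance by
#' sex.
#'
#' @param config run configuration; defaults to the standard cohort.
#' @param out_dir output directory (trials under `trials/`, statistics under
#'   `stats/`).
#' @param with_gaze simulate/analyze the gaze channel?
#' @return Invisibly, the [run_stats()] result list.
#' @export
run_report <- function(config = .default_run_config(), out_dir,
                       with_gaze = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_simulate(config, file.path(out_dir, "trials"), with_gaze = with_gaze)
  metrics <- run_analyze(file.path(out_dir, "trials"),
                         file.path(out_dir, "metrics.csv"),
                         hand = config$hand, gaze = config$gaze,
                         config = config)
  stats_out <- run_stats(metrics, file.path(out_dir, "stats"), config = config)
  trio <- stats_out$group_results[
    stats_out$group_results$metric %in%
      c("distance", "lag_ms", "residual_distance"), ]
  lines <- c(.provenance(config, config$cohort$seed),
             "Replication summary (raw distance, lag, residual by sex):",
             utils::capture.output(print(trio)))
  writeLines(lines, file.path(out_dir, "replication_summary.txt"))
  invisible(stats_out)
}
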