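#' Harmonic target pattern
#'
#' A 2D target trajectory built from a sum of sinusoids: one fundamental plus
#' one higher harmonic per axis,
#' \deqn{x(t) = A_{1x}\cos\omega t + A_{2x}\cos(h_x\omega t - \varphi_x)}
#' \deqn{y(t) = A_{1y}\sin\omega t + A_{2y}\sin(h_y\omega t - \varphi_y)}
#' This construction yields pseudo-random looking 2D paths with smooth
#' changes in velocity and direction. Amplitudes are in cm (screen-centered
#' coordinates, +x right, +y up), phases in degrees, and `omega` is the
#' fundamental angular frequency in rad/s (`2*pi/period_s`).
#'
#' @param pattern_id integer label (1-5 for the packaged set).
#' @param A1x,A2x,A1y,A2y sinusoid amplitudes, cm; must be > 0.
#' @param hx,hy integer harmonic multipliers, >= 2 (a second or third
#'   harmonic above the fundamental).
#' @param phi_x_deg,phi_y_deg phases of the harmonic terms, degrees.
#' @param period_s period of one full revolution of the figure, s (the
#'   standard patterns use 5 s, i.e. `omega = 2*pi/5`).
#' @return An object of class `harmonic_pattern`.
#' @examples
#' p <- harmonic_pattern(1, 5, 5, 2, 45, 5, 5, 3, -135)
#' target_position(p, 0)
#' @export
harmonic_pattern <- function(pattern_id, A1x, A2x, hx, phi_x_deg,
                             A1y, A2y, hy, phi_y_deg, period_s = 5) {
  for (nm in c("A1x", "A2x", "A1y", "A2y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("amplitude '%s' must be a single positive number", nm))
  }
  for (nm in c("hx", "hy")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v != round(v) || v < 2)
      stop(sprintf("harmonic multiplier '%s' must be an integer >= 2", nm))
  }
  if (!is.numeric(period_s) || period_s <= 0)
    stop("'period_s' must be positive")
  structure(
    list(pattern_id = as.integer(pattern_id),
         A1x = A1x, A2x = A2x, hx = as.integer(hx),
         phi_x = phi_x_deg * pi / 180,
         A1y = A1y, A2y = A2y, hy = as.integer(hy),
         phi_y = phi_y_deg * pi / 180,
         omega = 2 * pi / period_s),
    class = "harmonic_pattern")
}

#' @export
print.harmonic_pattern <- function(x, ...) {
  cat(sprintf("<harmonic_pattern %d>  omega = %.4f rad/s (period %.3g s)\n",
              x$pattern_id, x$omega, 2 * pi / x$omega))
  cat(sprintf("  x: %.3g cos(wt) + %.3g cos(%d wt - %.1f deg)\n",
              x$A1x, x$A2x, x$hx, x$phi_x * 180 / pi))
  cat(sprintf("  y: %.3g sin(wt) + %.3g sin(%d wt - %.1f deg)\n",
              x$A1y, x$A2y, x$hy, x$phi_y * 180 / pi))
  invisible(x)
}

#' Evaluate a harmonic pattern at given times
#'
#' Closed-form evaluation of the target position; no numerical integration is
#' involved. The trajectory is periodic with period `2*pi/omega`.
#'
#' @param pattern a [harmonic_pattern()].
#' @param t time or vector of times, s; must be finite and >= 0.
#' @return A matrix with columns `x`, `y` (cm), one row per time point.
#' @export
target_position <- function(pattern, t) {
  stopifnot(inherits(pattern, "harmonic_pattern"))
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)))
    stop("'t' must be finite numeric time(s) in seconds")
  if (any(t < 0)) stop("'t' must be >= 0")
  w <- pattern$omega
  x <- pattern$A1x * cos(w * t) +
    pattern$A2x * cos(pattern$hx * w * t - pattern$phi_x)
  y <- pattern$A1y * sin(w * t) +
    pattern$A2y * sin(pattern$hy * w * t - pattern$phi_y)
  cbind(x = x, y = y)
}

#' Sample a harmonic pattern at a fixed rate
#'
#' @param pattern a [harmonic_pattern()].
#' @param duration trial duration, s.
#' @param fs sampling rate, Hz. Must exceed twice the highest harmonic
#'   frequency of the pattern (Nyquist).
#' @return A `trajectory_series`: data.frame with columns `time`, `x`, `y`
#'   and attribute `fs`; sample `i` is taken at time `(i-1)/fs`.
#' @export
sample_trajectory <- function(pattern, duration = 10, fs = 1000) {
  stopifnot(inherits(pattern, "harmonic_pattern"))
  if (!is.numeric(duration) || duration <= 0) stop("'duration' must be > 0")
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be > 0")
  f_max <- max(pattern$hx, pattern$hy) * pattern$omega / (2 * pi)
  if (fs <= 2 * f_max)
    stop(sprintf("fs = %g Hz aliases the pattern: need fs > %g Hz", fs, 2 * f_max))
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  xy <- target_position(pattern, tt)
  out <- data.frame(time = tt, x = xy[, "x"], y = xy[, "y"])
  attr(out, "fs") <- fs
  class(out) <- c("trajectory_series", "data.frame")
  out
}

#' Path length of a sampled trajectory
#'
#' Sum of Euclidean increments between consecutive samples. Invariant under
#' rigid rotation and translation of the coordinate frame.
#'
#' @param series a `trajectory_series`, or any data.frame/matrix with `x` and
#'   `y` columns.
#' @return Path length, cm.
#' @export
path_length <- function(series) {
  xy <- .as_xy(series)
  if (nrow(xy) < 2L) stop("need at least 2 samples to compute a path length")
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

#' Mean tangential velocity of a sampled trajectory
#'
#' Path length divided by elapsed time; equals the time-average of the
#' instantaneous speed.
#'
#' @inheritParams path_length
#' @return Mean speed, cm/s.
#' @export
mean_target_speed <- function(series) {
  if (is.null(series$time)) stop("'series' must have a 'time' column")
  dur <- series$time[length(series$time)] - series$time[1]
  if (dur <= 0) stop("series spans zero duration")
  path_length(series) / dur
}

#' Load the packaged target pattern table
#'
#' Reads the five standard target patterns from a human-readable CSV shipped
#' with the package (columns `pattern_id, A1x, A2x, hx, phi_x_deg, A1y, A2y,
#' hy, phi_y_deg, period_s`). Each pattern combines a fundamental at
#' 1/`period_s` Hz with a second or third harmonic on each axis; over a 10-s
#' trial every pattern covers close to 160 cm of path at a mean speed close
#' to 16 cm/s.
#'
#' @param path optional path to an alternative parameter CSV with the same
#'   columns.
#' @return A list of 5 (or more) [harmonic_pattern()] objects, named by id.
#' @export
load_pattern_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "target_patterns.csv",
                        package = "visuotrack", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("pattern_id", "A1x", "A2x", "hx", "phi_x_deg",
            "A1y", "A2y", "hy", "phi_y_deg", "period_s")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pattern table is missing column(s): ", paste(miss, collapse = ", "))
  pats <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    tryCatch(
      harmonic_pattern(row$pattern_id, row$A1x, row$A2x, row$hx,
                       row$phi_x_deg, row$A1y, row$A2y, row$hy,
                       row$phi_y_deg, row$period_s),
      error = function(e)
        stop(sprintf("pattern table row %d (pattern_id %s): %s",
                     i, row$pattern_id, conditionMessage(e)), call. = FALSE))
  })
  names(pats) <- as.character(tab$pattern_id)
  pats
}

# Coerce matrix / data.frame input to an n x 2 numeric xy matrix.
.as_xy <- function(obj) {
  if (is.matrix(obj)) {
    if (ncol(obj) < 2L) stop("xy matrix needs two columns")
    xy <- obj[, 1:2, drop = FALSE]
  } else if (is.data.frame(obj)) {
    if (!all(c("x", "y") %in% names(obj)))
      stop("data.frame input needs 'x' and 'y' columns")
    xy <- cbind(obj$x, obj$y)
  } else stop("expected a matrix or data.frame of xy positions")
  storage.mode(xy) <- "double"
  if (any(!is.finite(xy))) stop("xy positions must be finite")
  xy
}
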