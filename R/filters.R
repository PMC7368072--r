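# Shared signal-conditioning helpers: zero-phase low-pass filtering with
# reflection padding (to suppress filter edge transients) and smoothed
# differentiation.

#' Zero-phase low-pass filter
#'
#' Second-order Butterworth filter applied forward and backward
#' ([signal::filtfilt()]), so the output has no phase shift. The input is
#' odd-reflection padded at both ends before filtering and cropped after, to
#' keep startup transients out of the data.
#'
#' @param x numeric vector.
#' @param cutoff_hz cutoff frequency, Hz. `Inf` returns `x` unchanged.
#' @param fs sampling rate, Hz.
#' @param order filter order (of the one-way filter; applied twice).
#' @return Filtered vector, same length as `x`.
#' @export
lowpass <- function(x, cutoff_hz, fs, order = 2) {
  if (!is.finite(cutoff_hz)) return(x)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("'cutoff_hz' must lie in (0, fs/2)")
  n <- length(x)
  np <- min(n - 1L, max(8L, ceiling(2 * fs / cutoff_hz)))
  # odd reflection about the end points preserves signal level and slope
  head_pad <- 2 * x[1] - x[seq(np + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - np)]
  bf <- .butter_cached(order, cutoff_hz / (fs / 2))
  y <- .filtfilt_ba(bf$b, bf$a, c(head_pad, x, tail_pad))
  y[seq(np + 1L, np + n)]
}

.butter_cache <- new.env(parent = emptyenv())

.butter_cached <- function(order, W) {
  key <- sprintf("%d_%.12g", order, W)
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    raw <- signal::butter(order, W, type = "low")
    bf <- list(b = as.numeric(raw$b), a = as.numeric(raw$a))
    .butter_cache[[key]] <- bf
  }
  bf
}

# One-way IIR filter, then the reverse pass (zero-phase). The MA and AR
# stages run in C via stats::filter. The filter state is initialized at the
# signal's first value (exact for unity DC gain), so a constant input passes
# through with no startup transient.
.filter_ba <- function(b, a, x) {
  x1 <- x[1L]
  dc <- sum(b) / sum(a)
  x <- x - x1
  nb <- length(b)
  z <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution",
                     sides = 1)
  z <- as.numeric(z)[nb:(nb - 1L + length(x))]
  if (length(a) > 1L)
    z <- as.numeric(stats::filter(z, -a[-1L] / a[1L], method = "recursive"))
  z / a[1L] + dc * x1
}

.filtfilt_ba <- function(b, a, x)
  rev(.filter_ba(b, a, rev(.filter_ba(b, a, x))))

# Central-difference derivative (one-sided at the ends), in units of
# x-units per second.
.derivative <- function(x, fs) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}
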