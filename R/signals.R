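#' Zero-lag low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and then backward over the
#' series so that the net phase shift is zero ("no-lag" filtering), the
#' standard conditioning step for motion-capture and force-plate channels
#' before differentiation or integration. The default is a second-order
#' filter with a 15 Hz cut-off.
#'
#' Before filtering, the series is extended at both ends by odd reflection
#' (mirrored about the end value) over `3 * (order + 1)` samples, and each
#' pass is initialised at the steady state of its first padded sample, so a
#' constant series is returned exactly unchanged and end transients are
#' confined to the padding.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param rate Sampling rate of `x` in Hz.
#' @param cutoff Low-pass cut-off frequency in Hz. Must be below the Nyquist
#'   frequency `rate / 2`.
#' @param order Filter order of each pass (default 2). The forward-backward
#'   combination doubles the effective roll-off.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 85)
#' noisy <- sin(2 * pi * t) + rnorm(length(t), sd = 0.05)
#' smooth <- lowpass_zero_lag(noisy, rate = 85)
#' @export
lowpass_zero_lag <- function(x, rate, cutoff = 15, order = 2) {
  stopifnot(is.numeric(x), length(rate) == 1, rate > 0, cutoff > 0)
  if (cutoff >= rate / 2) {
    stop("`cutoff` (", cutoff, " Hz) must be below the Nyquist frequency ",
         rate / 2, " Hz", call. = FALSE)
  }
  pad <- 3L * (order + 1L)
  n <- length(x)
  if (n <= pad) {
    stop("series of length ", n, " is too short for reflective padding of ",
         pad, " samples", call. = FALSE)
  }
  if (anyNA(x)) stop("`x` contains missing values", call. = FALSE)
  ba <- signal::butter(order, cutoff / (rate / 2), type = "low")
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- iir_once(xp, ba$b, ba$a)
  y <- rev(iir_once(rev(y), ba$b, ba$a))
  y[(pad + 1):(pad + n)]
}

# Single causal IIR pass initialised at the steady state of the first sample,
# so the DC gain (exactly 1 for a Butterworth low-pass) is honoured from the
# first output sample. MA part and AR part are run through stats::filter.
iir_once <- function(x, b, a) {
  stopifnot(a[1] == 1)
  k <- length(b) - 1L
  x0 <- x[1]
  xx <- c(rep(x0, k), x)
  v <- stats::filter(xx, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[(k + 1):length(xx)]
  y <- stats::filter(v, -a[-1], method = "recursive", init = rep(x0, k))
  as.numeric(y)
}

#' Resample a uniformly sampled series by linear interpolation
#'
#' Places the series on a new uniform grid at `rate` Hz spanning the original
#' time range. Linear interpolation reproduces affine signals exactly and, at
#' the rates involved here (force channels recorded in the kHz range brought
#' down to the 85 Hz common grid), its error on band-limited physiological
#' signals is far below measurement noise.
#'
#' @param x Numeric vector, uniformly sampled at `from_rate`.
#' @param rate Target sampling rate in Hz.
#' @param from_rate Original sampling rate of `x` in Hz.
#' @param t0 Time of the first sample in seconds (default 0); the output grid
#'   starts at the same instant.
#' @return Numeric vector on the new grid (last point at or before the end of
#'   the original range).
#' @export
resample_to <- function(x, rate, from_rate, t0 = 0) {
  stopifnot(is.numeric(x), rate > 0, from_rate > 0)
  if (length(x) < 2) stop("need at least 2 samples to resample", call. = FALSE)
  t_old <- t0 + (seq_along(x) - 1) / from_rate
  t_new <- resample_grid(length(x), rate, from_rate, t0)
  stats::approx(t_old, x, xout = t_new, method = "linear", rule = 2)$y
}

resample_grid <- function(n, rate, from_rate, t0 = 0) {
  t_end <- t0 + (n - 1) / from_rate
  seq(t0, t_end, by = 1 / rate)
}

#' Cumulative trapezoidal integration with a fixed initial value
#'
#' Integrates a uniformly sampled series with the trapezoidal rule, taking
#' the value at the first sample as the integration constant (default 0, the
#' "null constant" convention used when reconstructing centre-of-mass
#' velocity and displacement from quiet standing: both start at zero).
#'
#' @param x Numeric vector, uniformly sampled.
#' @param rate Sampling rate in Hz.
#' @param initial Value of the integral at the first sample.
#' @return Numeric vector of the same length as `x`; element 1 equals
#'   `initial`.
#' @examples
#' a <- rep(1, 86)                       # 1 m/s^2 over one second at 85 Hz
#' v <- integrate_trapezoid(a, rate = 85)
#' v[length(v)]                          # 1 m/s
#' @export
integrate_trapezoid <- function(x, rate, initial = 0) {
  stopifnot(is.numeric(x), rate > 0)
  if (length(x) < 2) stop("need at least 2 samples to integrate", call. = FALSE)
  t <- (seq_along(x) - 1) / rate
  as.numeric(pracma::cumtrapz(t, x)) + initial
}
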