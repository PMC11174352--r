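#' Backward finite-difference velocity of a kinematic trace
#'
#' Computes velocity as the backward first difference scaled by the sampling
#' rate, `v(t) = (y(t) - y(t - 1)) * F`, the convention used for markerless
#' CoM traces sampled at the common grid rate. The first sample, which has
#' no predecessor, is set equal to the second so no spurious start transient
#' is introduced.
#'
#' @param y Numeric vector, uniformly sampled position (m).
#' @param rate Sampling rate F in Hz.
#' @return Numeric vector of velocities (m/s), same length as `y`.
#' @examples
#' com_velocity_fd(c(0, 0.3, 0.6, 0.9) / 85 * 25.5, rate = 85)
#' @export
com_velocity_fd <- function(y, rate) {
  stopifnot(rate > 0)
  if (length(y) < 2) {
    stop("need at least 2 samples for a backward difference", call. = FALSE)
  }
  v <- c(NA_real_, diff(y)) * rate
  v[1] <- v[2]
  v
}

#' ML base of support from heel positions
#'
#' The markerless route measures the ML base of support directly as the
#' absolute ML distance between the two heels at the swing-foot contact
#' sample. Symmetric in its two heel arguments.
#'
#' @param left_heel_y,right_heel_y Numeric vectors, ML heel positions (m) on
#'   the common grid.
#' @param events A `gait_events` object or list with a `foot_contact` sample
#'   index.
#' @return Base of support (m).
#' @export
bos_from_heels <- function(left_heel_y, right_heel_y, events) {
  i <- events$foot_contact
  if (is.na(i) || i < 1 || i > length(left_heel_y) ||
      i > length(right_heel_y)) {
    stop("foot-contact index outside the heel channels", call. = FALSE)
  }
  l <- left_heel_y[i]
  r <- right_heel_y[i]
  if (is.na(l) || is.na(r)) {
    stop("heel channel missing at the foot-contact sample", call. = FALSE)
  }
  abs(l - r)
}
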