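#' Centre-of-mass acceleration from the ML ground reaction force
#'
#' Applies Newton's second law: the mediolateral CoM acceleration is the
#' summed ML ground reaction force across plates divided by body mass.
#'
#' @param f_ml Numeric vector, ML ground reaction force (N) summed over
#'   plates, on the common grid.
#' @param mass Body mass in kg.
#' @return Numeric vector of ML CoM acceleration (m/s^2).
#' @export
com_acceleration <- function(f_ml, mass) {
  if (!(is.numeric(mass) && length(mass) == 1 && mass > 0)) {
    stop("`mass` must be a single positive number", call. = FALSE)
  }
  f_ml / mass
}

#' Estimate body mass from the vertical force during quiet standing
#'
#' Averages the total vertical force over a static window preceding gait
#' onset and divides by g = 9.81 m/s^2. When body mass is available in the
#' trial metadata the metadata value is authoritative and this estimate
#' serves as a cross-check.
#'
#' @param fz Numeric vector, total vertical force (N).
#' @param rate Sampling rate in Hz.
#' @param static_window Two-element numeric, start and end (s) of the quiet
#'   standing window.
#' @return Estimated mass (kg). If the estimate is implausibly small
#'   (< 20 kg) a warning is raised and the attribute `quality_warning` is
#'   set on the result.
#' @export
estimate_mass <- function(fz, rate, static_window = c(0.05, 0.55)) {
  idx <- window_indices(static_window, rate, length(fz))
  if (length(idx) == 0) {
    stop("static window lies outside the recording", call. = FALSE)
  }
  m <- mean(fz[idx]) / GRAVITY
  if (m < 20) {
    warning("estimated mass ", signif(m, 3),
            " kg is implausibly small; check the vertical force channel",
            call. = FALSE)
    attr(m, "quality_warning") <- TRUE
  }
  m
}

window_indices <- function(window, rate, n) {
  lo <- max(1L, as.integer(floor(window[1] * rate)) + 1L)
  hi <- min(n, as.integer(ceiling(window[2] * rate)) + 1L)
  if (lo > hi) integer(0) else lo:hi
}

#' Mediolateral centre of pressure of one force plate
#'
#' For a surface-mounted plate the ML CoP is `-Mx / Fz` plus the plate's ML
#' origin offset in the global frame. Samples where the vertical force is at
#' or below the support threshold are returned as `NA` (plate unloaded).
#'
#' @param fz Vertical force (N).
#' @param mx Moment about the anteroposterior axis (N m).
#' @param offset ML position of the plate origin in the global frame (m).
#' @param threshold Minimum vertical force (N) for the CoP to be defined.
#' @param z_offset Vertical offset (m) of the plate surface above its
#'   measurement origin; the shear-force correction `z_offset * Fy / Fz`
#'   is applied when non-zero.
#' @param fy ML shear force (N), only needed when `z_offset` is non-zero.
#' @return Numeric vector of ML CoP (m) with `NA` where undefined.
#' @export
cop_ml <- function(fz, mx, offset = 0, threshold = 10, z_offset = 0,
                   fy = NULL) {
  stopifnot(length(fz) == length(mx))
  cop <- -mx / fz + offset
  if (z_offset != 0) {
    if (is.null(fy)) {
      stop("`fy` is required when `z_offset` is non-zero", call. = FALSE)
    }
    cop <- cop - z_offset * fy / fz
  }
  cop[!(fz > threshold)] <- NA_real_
  if (all(is.na(cop))) {
    stop("all samples below the support threshold; CoP undefined",
         call. = FALSE)
  }
  cop
}

# Fz-weighted combination of per-plate CoP traces. Plates below the support
# threshold do not contribute; equals the single-plate CoP when only one
# plate is loaded.
cop_combine <- function(cops, fzs, threshold = 10) {
  stopifnot(length(cops) == length(fzs))
  num <- 0
  den <- 0
  for (k in seq_along(cops)) {
    w <- ifelse(fzs[[k]] > threshold & !is.na(cops[[k]]), fzs[[k]], 0)
    cop_k <- ifelse(w > 0, cops[[k]], 0)
    num <- num + w * cop_k
    den <- den + w
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' ML base of support from the centre-of-pressure trace
#'
#' During gait initiation the ML CoP trace shows two quasi-plateaus, one per
#' single-stance phase: under the stance foot between swing foot-off and
#' foot contact, and under the landed foot just after contact. The ML base
#' of support is the absolute difference between the extremal CoP of the two
#' plateaus, each extremum taken toward that phase's support side.
#'
#' When the recording ends shortly after the first contact (the usual
#' two-plate layout), the second phase is approximated by a fixed window
#' after foot contact (`post_window`, default 0.2 s): the CoP settles onto
#' its second plateau a few tens of milliseconds after heel contact.
#'
#' @param cop Combined ML CoP (m) on the common grid; may contain `NA`.
#' @param rate Sampling rate in Hz.
#' @param events A `gait_events` object (see [detect_events()]) or a list
#'   with `onset`, `foot_off`, `foot_contact` sample indices.
#' @param post_window Length (s) of the second single-stance window.
#' @param static_window Quiet-standing window (s) used to orient the stance
#'   side.
#' @return The base of support (m), with attributes `stance_boundary` and
#'   `swing_boundary` (the two plateau extrema, global frame) and
#'   `stance_dir` (+1/-1, the global direction of the stance side).
#' @export
bos_from_cop <- function(cop, rate, events, post_window = 0.2,
                         static_window = c(0.05, 0.55)) {
  n <- length(cop)
  w1 <- events$foot_off:events$foot_contact
  w2 <- events$foot_contact:min(n, events$foot_contact +
                                  as.integer(round(post_window * rate)))
  c1 <- cop[w1][!is.na(cop[w1])]
  c2 <- cop[w2][!is.na(cop[w2])]
  if (length(c1) == 0 || length(c2) == 0) {
    stop("a single-stance window is empty or fully unloaded; cannot ",
         "extract CoP plateaus", call. = FALSE)
  }
  static_mean <- mean(cop[window_indices(static_window, rate, n)],
                      na.rm = TRUE)
  stance_dir <- sign(mean(c1) - static_mean)
  if (stance_dir == 0) stance_dir <- 1
  e1 <- if (stance_dir > 0) max(c1) else min(c1)   # toward the stance side
  e2 <- if (stance_dir > 0) min(c2) else max(c2)   # toward the landed side
  structure(abs(e2 - e1),
            stance_boundary = e1, swing_boundary = e2,
            stance_dir = stance_dir)
}

# Force-plate route CoM kinematics: acceleration by Newton's second law,
# velocity and displacement by successive trapezoidal integration with null
# integration constants, absolute position anchored at the quiet-standing
# mean CoP (static equilibrium puts the CoM above the CoP).
fps_com <- function(f_ml, mass, rate, anchor = 0) {
  acc <- com_acceleration(f_ml, mass)
  vel <- integrate_trapezoid(acc, rate, initial = 0)
  disp <- integrate_trapezoid(vel, rate, initial = 0)
  tibble::tibble(accel = acc, vel = vel, pos = disp + anchor)
}
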