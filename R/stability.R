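#' Inverted-pendulum length from body height
#'
#' The body is modelled as an inverted pendulum whose length is 57.5% of
#' body height.
#'
#' @param height Body height in m.
#' @return Pendulum length l in m.
#' @export
pendulum_length <- function(height) {
  if (!all(height > 0)) stop("height must be positive", call. = FALSE)
  0.575 * height
}

#' Eigenfrequency of the inverted pendulum
#'
#' `omega0 = sqrt(g / l)` with g = 9.81 m/s^2.
#'
#' @param l Pendulum length in m.
#' @return Eigenfrequency in 1/s.
#' @export
eigenfrequency <- function(l) {
  if (!all(l > 0)) stop("pendulum length must be positive", call. = FALSE)
  sqrt(GRAVITY / l)
}

#' Extrapolated centre of mass
#'
#' The dynamically relevant stability point: CoM position plus CoM velocity
#' divided by the pendulum eigenfrequency, `Y = y + v / omega0`.
#'
#' @param y CoM position (m).
#' @param v CoM velocity (m/s).
#' @param omega0 Pendulum eigenfrequency (1/s).
#' @return Extrapolated CoM position (m).
#' @export
extrapolated_com <- function(y, v, omega0) {
  if (!all(omega0 > 0)) stop("omega0 must be positive", call. = FALSE)
  y + v / omega0
}

#' Margin of stability
#'
#' `MoS = BoS - Y`, the distance from the extrapolated CoM to the base-of-
#' support boundary; positive values mean the extrapolated CoM lies inside
#' the base of support (dynamically stable).
#'
#' @param bos Base-of-support boundary coordinate (m), non-negative.
#' @param ycom_extrap Extrapolated CoM coordinate (m) in the same frame.
#' @return Margin of stability (m).
#' @export
margin_of_stability <- function(bos, ycom_extrap) {
  if (!all(bos >= 0)) stop("base of support must be non-negative",
                           call. = FALSE)
  bos - ycom_extrap
}

# ---------------------------------------------------------------------------
# Common-grid preparation: filter each block at its native rate, then bring
# everything onto the shared analysis grid by linear interpolation.
prepare_trial <- function(trial, rate = 85, cutoff = 15) {
  stopifnot(inherits(trial, "gait_trial"))
  meta <- trial$meta
  fr <- meta$force_rate
  kr <- meta$kin_rate
  plates <- sort(unique(trial$forces$plate))

  res_f <- function(x, filt = FALSE) {
    if (filt) x <- lowpass_zero_lag(x, rate = fr, cutoff = cutoff)
    resample_to(x, rate, fr)
  }
  res_k <- function(x, filt = FALSE) {
    if (filt) x <- lowpass_zero_lag(x, rate = kr, cutoff = cutoff)
    resample_to(x, rate, kr)
  }

  fb <- list()
  for (pl in plates) {
    ch <- trial$forces[trial$forces$plate == pl, ]
    off <- if (pl == 1) meta$plate1_offset_y else meta$plate2_offset_y
    fb[[as.character(pl)]] <- list(
      fy_raw = res_f(ch$fy), fz_raw = res_f(ch$fz), mx_raw = res_f(ch$mx),
      fy_filt = res_f(ch$fy, filt = TRUE),
      offset = off
    )
  }
  kin <- NULL
  if (!is.null(trial$kinematics)) {
    k <- trial$kinematics
    kin <- list(
      com_y_raw = res_k(k$com_y),
      com_y_filt = res_k(k$com_y, filt = TRUE),
      heel_left_y = res_k(k$heel_left_y),
      heel_left_y_filt = res_k(k$heel_left_y, filt = TRUE),
      heel_right_y = res_k(k$heel_right_y),
      heel_right_y_filt = res_k(k$heel_right_y, filt = TRUE),
      heel_left_z = res_k(k$heel_left_z),
      heel_right_z = res_k(k$heel_right_z)
    )
  }
  n <- min(c(vapply(fb, function(b) length(b$fy_raw), 1L),
             if (!is.null(kin)) vapply(kin, length, 1L)))
  fb <- lapply(fb, function(b) {
    b[setdiff(names(b), "offset")] <-
      lapply(b[setdiff(names(b), "offset")], function(x) x[seq_len(n)])
    b
  })
  if (!is.null(kin)) kin <- lapply(kin, function(x) x[seq_len(n)])

  cops <- lapply(fb, function(b) -b$mx_raw / b$fz_raw + b$offset)
  cops <- purrr::map2(cops, fb, function(cp, b) {
    cp[!(b$fz_raw > 10)] <- NA_real_
    cp
  })
  cop_comb <- cop_combine(cops, lapply(fb, function(b) b$fz_raw))

  list(meta = meta, rate = rate, n = n, plates = fb, kin = kin,
       cop = cop_comb,
       fy_total_filt = Reduce(`+`, lapply(fb, function(b) b$fy_filt)),
       fz_total_raw = Reduce(`+`, lapply(fb, function(b) b$fz_raw)))
}

first_sustained <- function(cond, k, from = 1L) {
  cond[is.na(cond)] <- FALSE
  n <- length(cond)
  if (from > n) return(NA_integer_)
  r <- rle(cond[from:n])
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0) return(NA_integer_)
  from + (ends[hit[1]] - r$lengths[hit[1]])
}

#' Detect gait-initiation events
#'
#' Detects onset, swing foot-off and swing foot-contact on the common
#' analysis grid from unfiltered channels (the zero-lag filter is acausal
#' and would smear step-like transitions across the true event time):
#'
#' * onset — first sample where the combined ML CoP deviates from its quiet
#'   standing mean by more than 2.5 standard deviations of the static
#'   window, sustained for 50 ms;
#' * foot-off — first sample after onset where the swing-heel vertical
#'   position rises above its static baseline, sustained for 30 ms
#'   (requires the kinematic block: with both feet initially on plate 1 a
#'   per-foot vertical force share is not observable);
#' * foot-contact — force route: first sample where plate-2 vertical force
#'   exceeds 10 N sustained for 20 ms; kinematic route: first sample after
#'   the swing-heel apex where the heel has returned to its baseline.
#'
#' One event set is detected per trial and shared by both measurement
#' routes, so between-route MoS differences reflect the measurement systems
#' and not event timing.
#'
#' @param trial A `gait_trial`.
#' @param source `"force"` (default) or `"kinematic"` for the foot-contact
#'   rule.
#' @param rate Common analysis grid rate (Hz).
#' @param static_window Quiet-standing window (s).
#' @return A `gait_events` list: sample indices `onset`, `foot_off`,
#'   `foot_contact`, plus `source` and `rate`.
#' @export
detect_events <- function(trial, source = c("force", "kinematic"),
                          rate = 85, static_window = c(0.05, 0.55)) {
  source <- match.arg(source)
  prep <- prepare_trial(trial, rate = rate)
  n <- prep$n
  idx_static <- window_indices(static_window, rate, n)

  cop <- prep$cop
  mu <- mean(cop[idx_static], na.rm = TRUE)
  sdv <- stats::sd(cop[idx_static], na.rm = TRUE)
  thr <- 2.5 * sdv
  k_on <- max(1L, as.integer(ceiling(0.05 * rate)))
  onset <- first_sustained(abs(cop - mu) > thr, k_on,
                           from = max(idx_static) + 1L)
  if (is.na(onset)) {
    stop("no gait-initiation onset found in the CoP trace", call. = FALSE)
  }

  if (is.null(prep$kin)) {
    stop("foot-off detection requires the kinematic block (swing-heel ",
         "vertical channel)", call. = FALSE)
  }
  swing_z <- if (trial$meta$swing_side == "left") prep$kin$heel_left_z else
    prep$kin$heel_right_z
  base_z <- mean(swing_z[idx_static])
  # anchor on the swing-heel apex (far above any noise), then walk back to
  # where the heel first rose past 20% of the lift: robust against the
  # smooth positional noise of markerless capture
  apex <- onset - 1L + which.max(swing_z[onset:n])
  lift <- swing_z[apex] - base_z
  if (lift < 0.01) {
    stop("no swing-heel lift found after onset (no-step trial?)",
         call. = FALSE)
  }
  thr_z <- base_z + max(0.2 * lift, 3 * stats::sd(swing_z[idx_static]))
  below <- which(swing_z[onset:apex] < thr_z)
  foot_off <- if (length(below) == 0) onset + 1L else
    onset + below[length(below)]

  k_fc <- max(1L, as.integer(ceiling(0.02 * rate)))
  if (source == "force") {
    p2 <- prep$plates[["2"]]
    if (is.null(p2)) {
      stop("foot-contact detection from force requires plate 2; use ",
           "source = \"kinematic\" for single-plate records", call. = FALSE)
    }
    foot_contact <- first_sustained(p2$fz_raw > 10, k_fc, from = foot_off)
    if (is.na(foot_contact)) {
      stop("plate-2 vertical force never crossed the contact threshold ",
           "(no-step trial)", call. = FALSE)
    }
  } else {
    apex <- foot_off - 1L + which.max(swing_z[foot_off:n])
    thr_dn <- base_z + max(0.001, 3 * stats::sd(swing_z[idx_static]))
    foot_contact <- first_sustained(swing_z < thr_dn, k_fc, from = apex)
    if (is.na(foot_contact)) {
      stop("swing heel never returned to baseline (no contact found)",
           call. = FALSE)
    }
  }
  if (!(onset < foot_off && foot_off < foot_contact)) {
    stop("detected events are not ordered onset < foot-off < foot-contact",
         call. = FALSE)
  }
  structure(list(onset = onset, foot_off = foot_off,
                 foot_contact = foot_contact, source = source, rate = rate),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events> (", x$source, " detection, ", x$rate, " Hz grid)\n",
      "  onset ", x$onset, ", foot-off ", x$foot_off, ", foot-contact ",
      x$foot_contact, "\n", sep = "")
  invisible(x)
}

#' Margin of stability of one trial for one measurement route
#'
#' Computes the MoS components at the swing-foot contact sample for the
#' force-plate route (`"fps"`: CoM kinematics by Newton's second law and
#' double trapezoidal integration, base of support from the CoP plateaus) or
#' the markerless route (`"mls"`: CoM position from the kinematic block,
#' velocity by backward finite difference, base of support from the
#' heel-to-heel distance).
#'
#' Because the base of support is a size while the CoM position is a
#' coordinate, both are re-expressed in a common frame before the MoS is
#' formed: origin at the stance-limb lateral base-of-support boundary at
#' foot contact (the stance-side CoP plateau extremum for the force route,
#' the stance-heel ML position for the kinematic route), axis positive
#' toward the swing side. In that frame the base of support is the swing-
#' side boundary coordinate, and `MoS = BoS - (y + v / omega0)` is invariant
#' under translations of the laboratory frame.
#'
#' @param trial A `gait_trial`.
#' @param route `"fps"` or `"mls"`.
#' @param events A `gait_events` object, usually from [detect_events()]; one
#'   event set should be shared by both routes.
#' @param rate Common analysis grid rate (Hz).
#' @param cutoff Zero-lag low-pass cut-off (Hz) applied to the kinematic
#'   chain of both routes.
#' @param static_window Quiet-standing window (s) used for the integration
#'   anchor and stance-side orientation.
#' @return A one-row tibble: `route`, `ycom_fc`, `vcom_fc` (boundary frame,
#'   positive toward the swing side), `l`, `omega0`, `ycom_extrap`, `bos`,
#'   `mos`, `stable`.
#' @export
mos_for_trial <- function(trial, route = c("fps", "mls"), events,
                          rate = 85, cutoff = 15,
                          static_window = c(0.05, 0.55)) {
  route <- match.arg(route)
  prep <- prepare_trial(trial, rate = rate, cutoff = cutoff)
  fc <- events$foot_contact
  if (is.na(fc) || fc > prep$n) {
    stop("foot-contact index outside the common grid", call. = FALSE)
  }
  l <- pendulum_length(trial$meta$height)
  om <- eigenfrequency(l)

  if (route == "fps") {
    anchor_idx <- window_indices(static_window, rate, prep$n)
    anchor <- mean(prep$cop[anchor_idx], na.rm = TRUE)
    ck <- fps_com(prep$fy_total_filt, trial$meta$mass, rate, anchor = anchor)
    bos <- bos_from_cop(prep$cop, rate, events,
                        static_window = static_window)
    b_st <- attr(bos, "stance_boundary")
    sdir <- attr(bos, "stance_dir")
    y_g <- ck$pos[fc]
    v_g <- ck$vel[fc]
  } else {
    if (is.null(prep$kin)) {
      stop("route \"mls\" needs the kinematic block: channels com_y, ",
           "heel_left_y, heel_right_y are missing", call. = FALSE)
    }
    y_filt <- prep$kin$com_y_filt
    v_filt <- com_velocity_fd(y_filt, rate)
    hl <- prep$kin$heel_left_y_filt
    hr <- prep$kin$heel_right_y_filt
    bos <- bos_from_heels(hl, hr, events)
    stance_heel <- if (trial$meta$swing_side == "left") hr else hl
    b_st <- stance_heel[fc]
    sdir <- sign(b_st - (hl[fc] + hr[fc]) / 2)
    if (sdir == 0) sdir <- 1
    y_g <- y_filt[fc]
    v_g <- v_filt[fc]
  }

  ycom_fc <- sdir * (b_st - y_g)
  vcom_fc <- -sdir * v_g
  ycom_extrap <- extrapolated_com(ycom_fc, vcom_fc, om)
  mos <- margin_of_stability(as.numeric(bos), ycom_extrap)
  tibble::tibble(
    route = toupper(route),
    ycom_fc = ycom_fc, vcom_fc = vcom_fc,
    l = l, omega0 = om,
    ycom_extrap = ycom_extrap,
    bos = as.numeric(bos), mos = mos,
    stable = mos > 0
  )
}

#' Margin of stability for every trial of a cohort
#'
#' Maps [detect_events()] and [mos_for_trial()] over a cohort tibble (as
#' produced by [make_cohort()], or any tibble with a `trial_data` list-column
#' of `gait_trial` objects). Events are detected once per trial and shared
#' by the requested routes.
#'
#' @param cohort Tibble with a `trial_data` list-column.
#' @param routes Character vector, subset of `c("fps", "mls")`.
#' @param events_source Detection source passed to [detect_events()].
#' @param ... Passed on to [mos_for_trial()].
#' @return A tibble with one row per trial and route: the cohort identifier
#'   columns plus the [mos_for_trial()] fields.
#' @examples
#' coh <- make_cohort(n_yh = 1, n_eh = 1, n_pd = 1,
#'                    trials_per_condition = 1, seed = 1)
#' compute_mos(coh)
#' @export
compute_mos <- function(cohort, routes = c("fps", "mls"),
                        events_source = "force", ...) {
  stopifnot(is.data.frame(cohort), "trial_data" %in% names(cohort))
  routes <- match.arg(routes, several.ok = TRUE)
  id_cols <- intersect(
    c("participant", "group", "condition", "trial", "swing_side",
      "mass", "height"),
    names(cohort)
  )
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    td <- cohort$trial_data[[i]]
    ev <- detect_events(td, source = events_source)
    res <- purrr::map_dfr(routes, function(r) {
      mos_for_trial(td, route = r, events = ev, ...)
    })
    dplyr::bind_cols(cohort[rep(i, nrow(res)), id_cols, drop = FALSE], res)
  })
}
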