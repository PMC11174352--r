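#' @importFrom rlang .data
NULL

GRAVITY <- 9.81

# Quintic polynomial through full endpoint states (position, velocity,
# acceleration at both ends). Returns coefficients c0..c5 of
# p(tau) = sum c_k tau^k on tau in [0, T].
quintic_coefs <- function(p0, v0, a0, p1, v1, a1, T) {
  c0 <- p0; c1 <- v0; c2 <- a0 / 2
  A <- rbind(
    c(T^3, T^4, T^5),
    c(3 * T^2, 4 * T^3, 5 * T^4),
    c(6 * T, 12 * T^2, 20 * T^3)
  )
  b <- c(
    p1 - (c0 + c1 * T + c2 * T^2),
    v1 - (c1 + 2 * c2 * T),
    a1 - 2 * c2
  )
  c(c0, c1, c2, solve(A, b))
}

quintic_eval <- function(coefs, tau, deriv = 0) {
  k <- 0:5
  out <- numeric(length(tau))
  for (j in k) {
    if (j < deriv) next
    fac <- prod(seq(j, by = -1, length.out = deriv))
    if (deriv == 0) fac <- 1
    out <- out + coefs[j + 1] * fac * tau^(j - deriv)
  }
  out
}

# Closed-form ML CoM trajectory in the stance-positive internal frame.
# Returns a list of vectorised functions y(t), v(t), a(t) plus the derived
# CoP trace and the analytic states at the event times.
ml_trajectory <- function(p) {
  w <- p$step_width
  half <- w / 2
  l <- pendulum_length(p$height)
  om <- eigenfrequency(l)
  t_on <- p$t_onset
  t_fo <- t_on + p$apa_duration
  t_fc <- t_fo + p$swing_duration
  lam <- p$transfer_rate

  v_fo <- 0.9 * p$com_peak_velocity
  y_fo <- half - sqrt((half - p$com_excursion)^2 + (v_fo / om)^2)
  a_fo <- om^2 * (y_fo - half)
  apa <- quintic_coefs(0, 0, 0, y_fo, v_fo, a_fo, p$apa_duration)

  # swing: inverted pendulum about the stance foot at +half
  c1s <- y_fo - half
  c2s <- v_fo / om
  y_fc <- half + c1s * cosh(om * p$swing_duration) + c2s * sinh(om * p$swing_duration)
  v_fc <- om * (c1s * sinh(om * p$swing_duration) + c2s * cosh(om * p$swing_duration))

  # after contact: CoP decays exponentially onto the landed foot at -half,
  # CoM follows the driven inverted-pendulum solution (still closed form)
  K <- om^2 * w / (om^2 - lam^2)
  c1p <- y_fc + half - K
  c2p <- (v_fc + lam * K) / om

  seg <- function(t) findInterval(t, c(t_on, t_fo, t_fc))
  fy <- function(t) {
    s <- seg(t); tau1 <- t - t_on; tau2 <- t - t_fo; tau3 <- t - t_fc
    ifelse(s == 0, 0,
    ifelse(s == 1, quintic_eval(apa, tau1),
    ifelse(s == 2, half + c1s * cosh(om * tau2) + c2s * sinh(om * tau2),
           -half + K * exp(-lam * tau3) + c1p * cosh(om * tau3) +
             c2p * sinh(om * tau3))))
  }
  fv <- function(t) {
    s <- seg(t); tau1 <- t - t_on; tau2 <- t - t_fo; tau3 <- t - t_fc
    ifelse(s == 0, 0,
    ifelse(s == 1, quintic_eval(apa, tau1, deriv = 1),
    ifelse(s == 2, om * (c1s * sinh(om * tau2) + c2s * cosh(om * tau2)),
           -lam * K * exp(-lam * tau3) +
             om * (c1p * sinh(om * tau3) + c2p * cosh(om * tau3)))))
  }
  fa <- function(t) {
    s <- seg(t); tau1 <- t - t_on; tau2 <- t - t_fo; tau3 <- t - t_fc
    ifelse(s == 0, 0,
    ifelse(s == 1, quintic_eval(apa, tau1, deriv = 2),
    ifelse(s == 2, om^2 * (c1s * cosh(om * tau2) + c2s * sinh(om * tau2)),
           lam^2 * K * exp(-lam * tau3) +
             om^2 * (c1p * cosh(om * tau3) + c2p * sinh(om * tau3)))))
  }
  fcop <- function(t) fy(t) - fa(t) / om^2
  # share of body weight carried by the landing plate
  fq <- function(t) ifelse(t < t_fc, 0, 1 - exp(-lam * (t - t_fc)))

  xcom_fc <- y_fc + v_fc / om
  list(
    y = fy, v = fv, a = fa, cop = fcop, q = fq,
    omega0 = om, l = l, half = half,
    t_onset = t_on, t_foot_off = t_fo, t_foot_contact = t_fc,
    y_fo = y_fo, v_fo = v_fo, y_fc = y_fc, v_fc = v_fc,
    xcom_fc = xcom_fc,
    # boundary frame: origin at the stance-side boundary, positive toward
    # the swing side
    ycom_extrap = half - xcom_fc,
    bos = w,
    mos = w - (half - xcom_fc)
  )
}

#' Simulate one gait-initiation trial with known ground truth
#'
#' Generates mutually consistent force-plate and kinematic channels for one
#' trial. In the noiseless channels, the ML ground reaction force equals mass
#' times the analytic CoM acceleration at every sample, and the combined CoP
#' equals `y - a / omega0^2` (the inverted-pendulum relation) at every
#' sample. Ground truth (analytic series, event times, BoS, extrapolated CoM
#' and MoS) is recorded before noise is added, so the full analysis pipeline
#' can be checked against exact values.
#'
#' The participant stands on plate 1 and the swing foot lands on plate 2;
#' plate-2 vertical force rises through the contact-detection threshold at
#' the true foot-contact time. The trial is deterministic given the profile
#' seed.
#'
#' @param profile A [gait_profile()].
#' @return An object of class `gait_trial`: a list with elements
#'   * `meta` — one-row tibble of trial metadata (participant, group,
#'     condition, mass, height, swing side, sampling rates, plate offsets);
#'   * `forces` — tibble of per-plate wrenches (`time`, `plate`, `fx`, `fy`,
#'     `fz`, `mx`, `my`, `mz`) at the force-plate rate;
#'   * `kinematics` — tibble (`time`, `com_x`, `com_y`, `com_z`,
#'     `heel_left_y`, `heel_left_z`, `heel_right_y`, `heel_right_z`) at the
#'     kinematic rate;
#'   * `truth` — `gait_truth` list: analytic `series` tibble (`time`,
#'     `com_y`, `com_vy`, `com_ay`, `cop_y` on the common grid, laboratory
#'     frame), event times and indices, and the scalar truths `bos`,
#'     `ycom_fc`, `vcom_fc`, `xcom_fc`, `ycom_extrap`, `mos`, `omega0`, `l`,
#'     `stance_dir`.
#' @examples
#' trial <- simulate_trial(gait_profile(seed = 7))
#' trial$truth$mos
#' @export
simulate_trial <- function(profile) {
  p <- validate_profile(profile)
  traj <- ml_trajectory(p)
  t_fc <- traj$t_foot_contact
  duration <- t_fc + p$tail
  # laboratory ML axis: positive toward the stance side of a left-swing
  # trial; right-swing trials are mirrored
  sdir <- if (p$swing_side == "left") 1 else -1
  half <- traj$half
  m <- p$mass

  ## ---- force block (native force-plate rate) ----
  tf <- seq(0, duration, by = 1 / p$force_rate)
  a_lab <- sdir * traj$a(tf)
  q <- traj$q(tf)
  fz_tot <- m * GRAVITY
  cop_lab <- sdir * traj$cop(tf)
  # plate 1 carries both feet before contact (its CoP is the combined CoP),
  # then the stance foot alone; plate 2 carries the landed foot
  cop1_lab <- ifelse(tf < t_fc, cop_lab, sdir * half)
  cop2_lab <- rep(-sdir * half, length(tf))
  fz1 <- fz_tot * (1 - q)
  fz2 <- fz_tot * q
  fy1 <- (1 - q) * m * a_lab
  fy2 <- q * m * a_lab
  # forward-progression force, not analysed but kept physiological in shape
  ax_ap <- progression_accel(tf, traj$t_foot_off, t_fc)
  fx1 <- (1 - q) * m * ax_ap
  fx2 <- q * m * ax_ap
  mx1 <- -cop1_lab * fz1
  mx2 <- -cop2_lab * fz2
  zero <- numeric(length(tf))
  forces <- dplyr::bind_rows(
    tibble::tibble(time = tf, plate = 1L, fx = fx1, fy = fy1, fz = fz1,
                   mx = mx1, my = zero, mz = zero),
    tibble::tibble(time = tf, plate = 2L, fx = fx2, fy = fy2, fz = fz2,
                   mx = mx2, my = zero, mz = zero)
  )

  ## ---- kinematic block ----
  tk <- seq(0, duration, by = 1 / p$kin_rate)
  com_y <- sdir * traj$y(tk)
  com_x <- progression_pos(tk, traj$t_foot_off, t_fc)
  com_z <- rep(traj$l, length(tk))
  swing_z <- heel_lift(tk, traj$t_foot_off, t_fc, p$step_height)
  stance_y <- rep(sdir * half, length(tk))
  swing_y <- rep(-sdir * half, length(tk))
  stance_z <- numeric(length(tk))
  if (p$swing_side == "left") {
    kin <- tibble::tibble(
      time = tk, com_x = com_x, com_y = com_y, com_z = com_z,
      heel_left_y = swing_y, heel_left_z = swing_z,
      heel_right_y = stance_y, heel_right_z = stance_z
    )
  } else {
    kin <- tibble::tibble(
      time = tk, com_x = com_x, com_y = com_y, com_z = com_z,
      heel_left_y = stance_y, heel_left_z = stance_z,
      heel_right_y = swing_y, heel_right_z = swing_z
    )
  }

  ## ---- ground truth (recorded before noise) ----
  truth <- list(
    series = tibble::tibble(
      time = tk,
      com_y = com_y,
      com_vy = sdir * traj$v(tk),
      com_ay = sdir * traj$a(tk),
      cop_y = sdir * traj$cop(tk)
    ),
    events = list(
      t_onset = traj$t_onset,
      t_foot_off = traj$t_foot_off,
      t_foot_contact = t_fc,
      onset = first_index_at(traj$t_onset, p$kin_rate),
      foot_off = first_index_at(traj$t_foot_off, p$kin_rate),
      foot_contact = first_index_at(t_fc, p$kin_rate)
    ),
    bos = traj$bos,
    step_width = p$step_width,
    ycom_fc = sdir * traj$y_fc,
    vcom_fc = sdir * traj$v_fc,
    xcom_fc = sdir * traj$xcom_fc,
    ycom_extrap = traj$ycom_extrap,
    mos = traj$mos,
    omega0 = traj$omega0,
    l = traj$l,
    stance_dir = sdir
  )
  class(truth) <- "gait_truth"

  ## ---- measurement noise, added after truth is frozen ----
  withr::with_seed(p$seed, {
    if (p$force_sd > 0 || p$moment_sd > 0) {
      nf <- nrow(forces)
      for (ch in c("fx", "fy", "fz")) {
        forces[[ch]] <- forces[[ch]] + stats::rnorm(nf, sd = p$force_sd)
      }
      for (ch in c("mx", "my", "mz")) {
        forces[[ch]] <- forces[[ch]] + stats::rnorm(nf, sd = p$moment_sd)
      }
    }
    if (p$kin_sd > 0) {
      for (ch in setdiff(names(kin), "time")) {
        kin[[ch]] <- kin[[ch]] +
          smooth_noise(length(tk), p$kin_rate, p$kin_sd, p$kin_noise_band)
      }
    }
  })
  if (p$bias_mls != 0) kin$com_y <- kin$com_y + p$bias_mls

  meta <- tibble::tibble(
    participant = NA_character_, group = p$group, condition = p$condition,
    trial = NA_integer_, mass = p$mass, height = p$height,
    swing_side = p$swing_side, force_rate = p$force_rate,
    kin_rate = p$kin_rate, plate1_offset_y = 0, plate2_offset_y = 0,
    single_plate = FALSE
  )
  structure(
    list(meta = meta, forces = forces, kinematics = kin, truth = truth),
    class = "gait_trial"
  )
}

# first sample of the common grid at or after an event time
first_index_at <- function(t_event, rate) {
  as.integer(ceiling(t_event * rate - 1e-9)) + 1L
}

# band-limited Gaussian noise rescaled to the target SD
smooth_noise <- function(n, rate, sd, band) {
  z <- stats::rnorm(n)
  if (band > 0 && band < rate / 2) {
    z <- lowpass_zero_lag(z, rate = rate, cutoff = band)
    s <- stats::sd(z)
    if (s > 0) z <- z / s
  }
  sd * z
}

# smooth forward progression of the CoM: at rest until foot-off, quintic
# smoothstep to 0.35 m by foot contact, then constant
progression_pos <- function(t, t_fo, t_fc) {
  u <- pmin(pmax((t - t_fo) / (t_fc - t_fo), 0), 1)
  0.35 * (10 * u^3 - 15 * u^4 + 6 * u^5)
}

progression_accel <- function(t, t_fo, t_fc) {
  T <- t_fc - t_fo
  u <- (t - t_fo) / T
  inside <- u > 0 & u < 1
  out <- numeric(length(t))
  out[inside] <- 0.35 * (60 * u[inside] - 180 * u[inside]^2 +
                           120 * u[inside]^3) / T^2
  out
}

# C2 vertical swing-heel lift: zero outside the swing phase
heel_lift <- function(t, t_fo, t_fc, height) {
  u <- (t - t_fo) / (t_fc - t_fo)
  inside <- u > 0 & u < 1
  out <- numeric(length(t))
  out[inside] <- height * 64 * u[inside]^3 * (1 - u[inside])^3
  out
}

#' Ground-truth events of a simulated trial
#'
#' Wraps the generator's true event indices as a `gait_events` object, so
#' the analysis can be run with exact event timing (bypassing detection) on
#' simulated data.
#'
#' @param trial A `gait_trial` from [simulate_trial()] (must carry truth).
#' @param rate Common grid rate the truth indices refer to (Hz).
#' @return A `gait_events` object with `source = "ground-truth"`.
#' @export
truth_events <- function(trial, rate = 85) {
  if (is.null(trial$truth)) {
    stop("trial carries no ground truth (only simulated trials do)",
         call. = FALSE)
  }
  ev <- trial$truth$events
  structure(list(onset = ev$onset, foot_off = ev$foot_off,
                 foot_contact = ev$foot_contact, source = "ground-truth",
                 rate = rate),
            class = "gait_events")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial> ", x$meta$group, "/", x$meta$condition,
      ", swing ", x$meta$swing_side, ", mass ", round(x$meta$mass, 1),
      " kg, height ", round(x$meta$height, 2), " m\n", sep = "")
  cat("  forces: ", nrow(x$forces) / 2, " samples/plate at ",
      x$meta$force_rate, " Hz;  kinematics: ", nrow(x$kinematics),
      " samples at ", x$meta$kin_rate, " Hz\n", sep = "")
  if (!is.null(x$truth)) {
    cat("  truth: BoS ", signif(x$truth$bos, 4), " m, MoS ",
        signif(x$truth$mos, 4), " m\n", sep = "")
  }
  invisible(x)
}

#' Generate a balanced synthetic cohort of gait-initiation trials
#'
#' Builds a cohort across the three groups (young healthy, elderly healthy,
#' Parkinson's disease) and two velocity conditions (spontaneous and
#' maximum), with per-participant anthropometrics drawn from the cohort
#' distributions and lognormal between-participant and between-trial
#' variability on the waveform parameters. The default sizes (10 YH, 11 EH,
#' 12 PD participants, five trials per velocity condition) yield 330 trials.
#'
#' @param n_yh,n_eh,n_pd Participants per group.
#' @param trials_per_condition Trials per participant and velocity condition.
#' @param seed Integer seed; the whole cohort (anthropometrics, waveform
#'   variability, per-trial noise) is deterministic given it.
#' @param anthropometrics Tibble of per-group mass/height means and SDs; see
#'   `gaitmos:::anthropometrics_default()` for the expected columns.
#' @param bias_mls Constant markerless CoM offset (m) applied to every trial,
#'   to inject a known inter-system bias (default 0).
#' @param ... Further arguments passed on to every [gait_profile()] call
#'   (e.g. `kin_sd`, `force_sd`, `kin_noise_band`).
#' @return A tibble with one row per trial: `participant`, `group`,
#'   `condition`, `trial`, `swing_side`, `mass`, `height`, `seed`, and a
#'   `trial_data` list-column of [simulate_trial()] results.
#' @examples
#' small <- make_cohort(n_yh = 1, n_eh = 1, n_pd = 1,
#'                      trials_per_condition = 1, seed = 1)
#' nrow(small)  # 3 groups x 2 conditions
#' @export
make_cohort <- function(n_yh = 10, n_eh = 11, n_pd = 12,
                        trials_per_condition = 5, seed = 1L,
                        anthropometrics = anthropometrics_default(),
                        bias_mls = 0, ...) {
  stopifnot(n_yh >= 1, n_eh >= 1, n_pd >= 1)
  if (trials_per_condition < 1) stop("zero trials requested", call. = FALSE)
  base <- group_baselines()

  design <- withr::with_seed(as.integer(seed), {
    participants <- purrr::pmap_dfr(
      list(g = c("YH", "EH", "PD"), n = c(n_yh, n_eh, n_pd)),
      function(g, n) {
        ant <- anthropometrics[anthropometrics$group == g, ]
        tibble::tibble(
          participant = sprintf("%s%02d", g, seq_len(n)),
          group = g,
          mass = clamp_positive(stats::rnorm(n, ant$mass_mean, ant$mass_sd),
                                ant$mass_mean),
          height = clamp_positive(stats::rnorm(n, ant$height_mean,
                                               ant$height_sd),
                                  ant$height_mean),
          exc_mult = stats::rlnorm(n, 0, 0.08),
          vel_mult = stats::rlnorm(n, 0, 0.08),
          width_mult = stats::rlnorm(n, 0, 0.05)
        )
      }
    )
    grid <- tidyr::expand_grid(
      participants,
      condition = c("SVC", "MVC"),
      trial = seq_len(trials_per_condition)
    )
    # one protocol-fixed starting leg for the whole cohort, as in a typical
    # instructed gait-initiation protocol
    grid$swing_side <- "left"
    n_tr <- nrow(grid)
    grid$trial_exc <- stats::rlnorm(n_tr, 0, 0.04)
    grid$trial_vel <- stats::rlnorm(n_tr, 0, 0.04)
    grid$trial_apa <- stats::rlnorm(n_tr, 0, 0.05)
    grid$trial_swing <- stats::rlnorm(n_tr, 0, 0.05)
    grid$onset_jitter <- stats::runif(n_tr, -0.05, 0.05)
    grid$seed <- sample.int(.Machine$integer.max - 1L, n_tr)
    grid
  })

  extra <- list(...)
  design <- dplyr::left_join(design, base, by = "group")
  design$trial_data <- purrr::pmap(design, function(...) {
    row <- list(...)
    mvc <- row$condition == "MVC"
    args <- c(list(
      group = row$group, condition = row$condition,
      mass = row$mass, height = row$height, swing_side = row$swing_side,
      step_width = row$step_width * row$width_mult,
      com_excursion = min(
        row$com_excursion * row$exc_mult * row$trial_exc,
        0.45 * row$step_width * row$width_mult
      ),
      com_peak_velocity = row$com_peak_velocity *
        (if (mvc) 1.25 else 1) * row$vel_mult * row$trial_vel,
      t_onset = 0.6 + row$onset_jitter,
      apa_duration = (row$apa_duration - (if (mvc) 0.10 else 0)) *
        row$trial_apa,
      swing_duration = (row$swing_duration - (if (mvc) 0.04 else 0)) *
        row$trial_swing,
      bias_mls = bias_mls,
      seed = row$seed
    ), extra)
    simulate_trial(do.call(gait_profile, args))
  })
  design$trial_data <- purrr::pmap(
    list(design$trial_data, design$participant, design$trial),
    function(td, id, k) {
      td$meta$participant <- id
      td$meta$trial <- as.integer(k)
      td
    }
  )
  dplyr::select(
    design, "participant", "group", "condition", "trial", "swing_side",
    "mass", "height", "seed", "trial_data"
  )
}

clamp_positive <- function(x, center) {
  pmax(x, 0.5 * center)
}
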