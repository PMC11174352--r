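#' Describe one synthetic gait-initiation trial
#'
#' A gait profile collects everything needed to generate a trial with
#' analytically known ground truth: anthropometrics, the mediolateral (ML)
#' waveform parameters, event times, sampling rates and the per-system
#' measurement-noise model. The ML centre-of-mass (CoM) trajectory is built
#' from closed-form C2 segments (quintic anticipatory phase, inverted-pendulum
#' single stance, exponential weight transfer after foot contact), so
#' acceleration, forces and centre of pressure (CoP) are exact by
#' construction, never numerically differentiated.
#'
#' Defaults are calibrated so that a trial shows the group-level magnitudes
#' reported for gait initiation in adults: ML base of support around 0.14 m,
#' extrapolated-CoM coordinate around 0.05 m from the stance-side boundary,
#' hence a margin of stability around 0.09 m.
#'
#' @param group Cohort label, one of `"YH"` (young healthy), `"EH"` (elderly
#'   healthy), `"PD"` (Parkinson's disease).
#' @param condition Velocity condition, `"SVC"` (spontaneous) or `"MVC"`
#'   (maximum).
#' @param mass Body mass in kg.
#' @param height Body height in m.
#' @param swing_side Which foot steps first, `"left"` or `"right"`.
#' @param step_width ML heel-to-heel distance (m), both at quiet standing and
#'   at swing-foot landing; this is the true ML base of support.
#' @param com_excursion Peak ML CoM shift toward the stance side (m). Must be
#'   smaller than `step_width / 2`.
#' @param com_peak_velocity Peak ML CoM velocity toward the stance side
#'   (m/s), reached shortly before foot-off.
#' @param t_onset Time of gait-initiation onset (s).
#' @param apa_duration Duration of the anticipatory phase, onset to swing
#'   foot-off (s).
#' @param swing_duration Swing phase duration, foot-off to foot contact (s).
#' @param tail Recording time kept after foot contact (s).
#' @param transfer_rate Exponential rate (1/s) of the body-weight and CoP
#'   transfer from the stance foot to the landed foot after contact; the
#'   default 40/s puts the CoP on its second plateau a few tens of
#'   milliseconds after heel contact.
#' @param step_height Peak vertical swing-heel lift (m).
#' @param force_rate Sampling rate of the force-plate channels (Hz).
#' @param kin_rate Sampling rate of the kinematic channels (Hz); also the
#'   common analysis grid.
#' @param force_sd,moment_sd Zero-mean Gaussian noise SD added to each force
#'   (N) and moment (N m) channel.
#' @param kin_sd Noise SD (m) added to each kinematic position channel.
#' @param kin_noise_band Bandwidth (Hz) of the kinematic noise: white noise
#'   is low-passed (zero-lag) at this cut-off and rescaled to `kin_sd`,
#'   emulating the smooth pose-model jitter of markerless capture rather
#'   than frame-wise white noise.
#' @param bias_mls Constant offset (m) added to the markerless CoM ML channel
#'   in the laboratory frame (positive toward the stance side of a
#'   left-swing trial). Used to inject a known inter-system bias; the
#'   default 0 means the generator itself assumes no systematic
#'   disagreement between systems.
#' @param seed Integer seed controlling all noise in the trial.
#' @return An object of class `gait_profile` (a named list).
#' @seealso [simulate_trial()], [make_cohort()]
#' @export
gait_profile <- function(group = "YH",
                         condition = "SVC",
                         mass = 70,
                         height = 1.70,
                         swing_side = "left",
                         step_width = 0.14,
                         com_excursion = 0.030,
                         com_peak_velocity = 0.111,
                         t_onset = 0.6,
                         apa_duration = 0.55,
                         swing_duration = 0.30,
                         tail = 0.40,
                         transfer_rate = 40,
                         step_height = 0.05,
                         force_rate = 1000,
                         kin_rate = 85,
                         force_sd = 2,
                         moment_sd = 0.2,
                         kin_sd = 0.003,
                         kin_noise_band = 3,
                         bias_mls = 0,
                         seed = 1L) {
  group <- match.arg(group, c("YH", "EH", "PD"))
  condition <- match.arg(condition, c("SVC", "MVC"))
  swing_side <- match.arg(swing_side, c("left", "right"))
  p <- list(
    group = group, condition = condition, mass = mass, height = height,
    swing_side = swing_side, step_width = step_width,
    com_excursion = com_excursion, com_peak_velocity = com_peak_velocity,
    t_onset = t_onset, apa_duration = apa_duration,
    swing_duration = swing_duration, tail = tail,
    transfer_rate = transfer_rate, step_height = step_height,
    force_rate = force_rate, kin_rate = kin_rate,
    force_sd = force_sd, moment_sd = moment_sd, kin_sd = kin_sd,
    kin_noise_band = kin_noise_band, bias_mls = bias_mls,
    seed = as.integer(seed)
  )
  class(p) <- "gait_profile"
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  with(p, {
    if (!(mass > 0)) stop("body mass must be positive", call. = FALSE)
    if (!(height > 0)) stop("body height must be positive", call. = FALSE)
    if (!(step_width > 0)) stop("step width must be positive", call. = FALSE)
    if (!(force_rate > 0 && kin_rate > 0)) {
      stop("sampling rates must be positive", call. = FALSE)
    }
    if (any(c(force_sd, moment_sd, kin_sd) < 0)) {
      stop("noise SDs must be non-negative", call. = FALSE)
    }
    if (!(t_onset > 0 && apa_duration > 0 && swing_duration > 0 && tail > 0)) {
      stop("event times must satisfy 0 < onset < foot-off < foot-contact < ",
           "duration", call. = FALSE)
    }
    if (!(com_excursion > 0 && com_excursion < step_width / 2)) {
      stop("`com_excursion` must lie in (0, step_width / 2): the CoM peak ",
           "must stay on the near side of the stance foot", call. = FALSE)
    }
    if (!(com_peak_velocity > 0)) {
      stop("`com_peak_velocity` must be positive", call. = FALSE)
    }
    if (!(transfer_rate > 0)) {
      stop("`transfer_rate` must be positive", call. = FALSE)
    }
  })
  invisible(p)
}

#' @export
print.gait_profile <- function(x, ...) {
  cat("<gait_profile> ", x$group, "/", x$condition,
      "  mass ", x$mass, " kg, height ", x$height, " m, swing ",
      x$swing_side, "\n", sep = "")
  cat("  step width ", x$step_width, " m, CoM excursion ", x$com_excursion,
      " m, peak ML velocity ", x$com_peak_velocity, " m/s\n", sep = "")
  cat("  events (s): onset ", x$t_onset, ", foot-off ",
      x$t_onset + x$apa_duration, ", foot-contact ",
      x$t_onset + x$apa_duration + x$swing_duration, "\n", sep = "")
  invisible(x)
}

# Group- and condition-level waveform baselines used by make_cohort().
# Slower, narrower gait initiation for the elderly and PD cohorts gives the
# group effect on MoS; the maximum-velocity condition is faster and raises
# the MoS, mirroring the velocity effect seen in gait-initiation studies.
group_baselines <- function() {
  tibble::tribble(
    ~group, ~step_width, ~com_excursion, ~com_peak_velocity, ~apa_duration, ~swing_duration,
    "YH",   0.145,       0.030,          0.111,              0.55,          0.30,
    "EH",   0.140,       0.029,          0.096,              0.60,          0.32,
    "PD",   0.130,       0.028,          0.083,              0.70,          0.34
  )
}

# Anthropometric distributions per cohort (means and SDs).
anthropometrics_default <- function() {
  tibble::tribble(
    ~group, ~n,  ~mass_mean, ~mass_sd, ~height_mean, ~height_sd,
    "PD",   12L, 70.5,       11.8,     1.70,         0.07,
    "YH",   10L, 70.2,       13.5,     1.70,         0.12,
    "EH",   11L, 63.9,       10.1,     1.65,         0.06
  )
}
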