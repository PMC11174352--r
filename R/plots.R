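#' Bland-Altman plot
#'
#' Difference against pair mean, one panel per stratum, with the bias (solid
#' line) and the 95% limits of agreement (dashed lines).
#'
#' @param object A `gaitmos_ba` table from [bland_altman()].
#' @param pairs The paired table the summaries were computed from; needed
#'   for the per-trial points.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gaitmos_ba <- function(object, pairs, ...) {
  by <- intersect(c("group", "condition"), names(object))
  p <- ggplot2::ggplot(pairs,
                       ggplot2::aes(x = .data$pair_mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(data = object,
                        ggplot2::aes(yintercept = .data$bias),
                        colour = "blue") +
    ggplot2::geom_hline(data = object,
                        ggplot2::aes(yintercept = .data$loa_lower),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(data = object,
                        ggplot2::aes(yintercept = .data$loa_upper),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "mean MoS of the two systems (m)",
                  y = "MoS difference, force plate - markerless (m)") +
    ggplot2::theme_minimal()
  if (length(by) == 2) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$condition),
      cols = ggplot2::vars(.data$group)
    )
  } else if (length(by) == 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(!!rlang::sym(by)))
  }
  p
}

#' Bayes-factor robustness curve
#'
#' BF01 as a function of the Cauchy prior scale, with the three conventional
#' scales marked and the BF01 = 3 moderate-evidence line.
#'
#' @param bf A `gaitmos_bf` object from [jzs_bf01()].
#' @return A ggplot object.
#' @export
plot_bf_robustness <- function(bf) {
  ggplot2::ggplot(bf$robustness, ggplot2::aes(x = .data$r, y = .data$bf01)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = bf$scales,
                        ggplot2::aes(shape = .data$prior), size = 3) +
    ggplot2::geom_hline(yintercept = 3, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Cauchy prior scale r",
                  y = expression(BF["01"]),
                  shape = "prior") +
    ggplot2::theme_minimal()
}

#' Plot the mediolateral traces of one trial
#'
#' Shows the ML CoM position of both measurement routes and the combined ML
#' CoP on the common grid, with the detected events marked; the classic
#' inspection figure for a gait-initiation trial.
#'
#' @param trial A `gait_trial`.
#' @param events Optional `gait_events`; detected from force by default.
#' @param rate,cutoff Common grid rate and filter cut-off.
#' @return A ggplot object.
#' @export
plot_trial_traces <- function(trial, events = NULL, rate = 85, cutoff = 15) {
  prep <- prepare_trial(trial, rate = rate, cutoff = cutoff)
  if (is.null(events)) events <- detect_events(trial, rate = rate)
  anchor_idx <- window_indices(c(0.05, 0.55), rate, prep$n)
  anchor <- mean(prep$cop[anchor_idx], na.rm = TRUE)
  fps <- fps_com(prep$fy_total_filt, trial$meta$mass, rate, anchor = anchor)
  tt <- (seq_len(prep$n) - 1) / rate
  df <- dplyr::bind_rows(
    tibble::tibble(time = tt, value = fps$pos,
                   trace = "CoM (force plates)"),
    if (!is.null(prep$kin)) {
      tibble::tibble(time = tt, value = prep$kin$com_y_filt,
                     trace = "CoM (markerless)")
    },
    tibble::tibble(time = tt, value = prep$cop, trace = "CoP (combined)")
  )
  ev <- tibble::tibble(
    time = (c(events$onset, events$foot_off, events$foot_contact) - 1) / rate,
    event = c("onset", "foot-off", "foot-contact")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = ev,
                        ggplot2::aes(xintercept = .data$time,
                                     linetype = .data$event),
                        colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "mediolateral position (m)",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
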