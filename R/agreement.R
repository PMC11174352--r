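#' Pair the two measurement routes trial by trial
#'
#' Reshapes a long MoS table (one row per trial and route, as returned by
#' [compute_mos()]) into one row per trial with both systems' MoS, the pair
#' mean, the difference (force-plate minus markerless) and the relative
#' difference as a percentage of the pair mean. Rows whose pair mean is zero
#' have an undefined relative difference and are flagged
#' (`rel_undefined = TRUE`); they are excluded from relative summaries.
#'
#' @param mos_long Tibble with at least `route` and `mos` columns plus
#'   identifier columns.
#' @return A paired tibble with `mos_fps`, `mos_mls`, `pair_mean`, `diff`,
#'   `rel_diff` (%), `rel_undefined`.
#' @export
pair_mos <- function(mos_long) {
  stopifnot(all(c("route", "mos") %in% names(mos_long)))
  id_cols <- intersect(
    c("participant", "group", "condition", "trial"), names(mos_long)
  )
  wide <- tidyr::pivot_wider(
    mos_long[, c(id_cols, "route", "mos")],
    names_from = "route", values_from = "mos"
  )
  if (!all(c("FPS", "MLS") %in% names(wide))) {
    stop("both routes (FPS and MLS) are needed to pair trials",
         call. = FALSE)
  }
  out <- dplyr::rename(wide, mos_fps = "FPS", mos_mls = "MLS")
  out <- dplyr::filter(out, !is.na(.data$mos_fps) & !is.na(.data$mos_mls))
  if (nrow(out) == 0) stop("no complete pairs", call. = FALSE)
  dplyr::mutate(
    out,
    pair_mean = (.data$mos_fps + .data$mos_mls) / 2,
    diff = .data$mos_fps - .data$mos_mls,
    rel_undefined = .data$pair_mean == 0,
    rel_diff = ifelse(.data$rel_undefined, NA_real_,
                      100 * .data$diff / .data$pair_mean)
  )
}

#' Bland-Altman agreement analysis
#'
#' For each stratum (by default every group x velocity-condition cell) the
#' lack of agreement between the two systems is summarised by the bias
#' (mean difference), the standard deviation of the differences, and the
#' 95% limits of agreement `bias +/- 1.96 SD`, in absolute units and as
#' percentages of the pair mean. Normality of the absolute differences is
#' checked with the Shapiro-Wilk test, and a product-moment correlation of
#' difference against pair mean tests whether the bias changes with the
#' magnitude of the MoS.
#'
#' @param pairs A paired table from [pair_mos()], or any data frame with
#'   `diff`, `pair_mean` and (if `by` is used) the stratification columns.
#' @param by Character vector of stratification columns; use `character(0)`
#'   for a single pooled analysis.
#' @return A tibble of class `gaitmos_ba`, one row per stratum: `n`, `bias`,
#'   `sd_diff`, `loa_lower`, `loa_upper` (m), `rel_bias`, `rel_loa_lower`,
#'   `rel_loa_upper` (%), `shapiro_w`, `shapiro_p`, `trend_r`, `trend_p`.
#' @export
bland_altman <- function(pairs, by = c("group", "condition")) {
  stopifnot(is.data.frame(pairs), all(c("diff", "pair_mean") %in%
                                        names(pairs)))
  by <- intersect(by, names(pairs))
  if (nrow(pairs) == 0) stop("empty paired table", call. = FALSE)
  grouped <- if (length(by) > 0) {
    dplyr::group_by(pairs, dplyr::across(dplyr::all_of(by)))
  } else {
    pairs
  }
  out <- dplyr::summarise(grouped, ba_one(dplyr::pick(dplyr::everything())),
                          .groups = "drop")
  bad <- out$n < 2
  if (any(bad)) {
    stop("stratum with fewer than 2 pairs: ",
         paste(do.call(paste, c(out[bad, by, drop = FALSE], sep = "/")),
               collapse = ", "), call. = FALSE)
  }
  class(out) <- c("gaitmos_ba", class(out))
  out
}

ba_one <- function(df) {
  d <- df$diff
  n <- length(d)
  bias <- mean(d)
  sdd <- stats::sd(d)
  rel <- if ("rel_diff" %in% names(df)) {
    df$rel_diff[!is.na(df$rel_diff)]
  } else {
    m <- df$pair_mean
    100 * d[m != 0] / m[m != 0]
  }
  rel_bias <- if (length(rel) > 0) mean(rel) else NA_real_
  rel_sd <- if (length(rel) > 1) stats::sd(rel) else NA_real_
  sw <- if (n >= 3 && isTRUE(sdd > 0)) {
    tryCatch(stats::shapiro.test(d), error = function(e) NULL)
  }
  tr <- if (n >= 3 && isTRUE(sdd > 0) && stats::sd(df$pair_mean) > 0) {
    stats::cor.test(df$pair_mean, d)
  }
  tibble::tibble(
    n = n, bias = bias, sd_diff = sdd,
    loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
    rel_bias = rel_bias,
    rel_loa_lower = rel_bias - 1.96 * rel_sd,
    rel_loa_upper = rel_bias + 1.96 * rel_sd,
    shapiro_w = if (is.null(sw)) NA_real_ else unname(sw$statistic),
    shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
    trend_r = if (is.null(tr)) NA_real_ else unname(tr$estimate),
    trend_p = if (is.null(tr)) NA_real_ else tr$p.value
  )
}

#' Factorial ANOVA on trial-level MoS
#'
#' Fits a three-factor factorial linear model on trial-level MoS
#' observations — measurement system and velocity condition crossed with
#' group, all interactions — and reports Type II sums of squares, which
#' coincide with the classical balanced-design decomposition when the group
#' sizes are balanced and remain well defined for the unequal group sizes of
#' a typical cohort. With `aggregate = TRUE` trials are first averaged
#' within participant x condition x system, giving the subject-level
#' variant.
#'
#' @param mos_long Tibble with `mos`, `route`, `condition`, `group` columns
#'   (one row per trial and route), e.g. from [compute_mos()].
#' @param aggregate Average trials within participant x condition x system
#'   before fitting (default `FALSE`: trial-level observations).
#' @return An object of class `gaitmos_anova` with the Type II table
#'   (effect, sum of squares, df, F, p), residual line included; access it
#'   tidily via [generics::tidy()].
#' @export
mos_anova <- function(mos_long, aggregate = FALSE) {
  need <- c("mos", "route", "condition", "group")
  stopifnot(all(need %in% names(mos_long)))
  df <- mos_long
  if (aggregate) {
    df <- dplyr::summarise(
      dplyr::group_by(df, .data$participant, .data$group, .data$condition,
                      .data$route),
      mos = mean(.data$mos), .groups = "drop"
    )
  }
  df <- dplyr::mutate(
    df,
    system = factor(.data$route),
    velocity = factor(.data$condition),
    group = factor(.data$group)
  )
  cells <- table(df$system, df$velocity, df$group)
  if (any(cells == 0)) {
    stop("empty design cell: every system x velocity x group combination ",
         "needs at least one observation", call. = FALSE)
  }
  fit <- stats::lm(mos ~ system * velocity * group, data = df)
  ss_resid <- sum(stats::residuals(fit)^2)
  tab <- if (ss_resid > 1e-25) {
    a <- car::Anova(fit, type = 2)
    tibble::tibble(
      term = rownames(a),
      sumsq = a[["Sum Sq"]],
      df = a[["Df"]],
      statistic = a[["F value"]],
      p.value = a[["Pr(>F)"]]
    )
  } else {
    # degenerate data (zero residual variance): report the sums of squares,
    # leave F undefined
    a <- suppressWarnings(stats::anova(fit))
    tibble::tibble(
      term = c(rownames(a)),
      sumsq = a[["Sum Sq"]],
      df = a[["Df"]],
      statistic = NA_real_,
      p.value = NA_real_
    )
  }
  structure(
    list(table = tab, fit = fit, n = nrow(df), aggregate = aggregate),
    class = "gaitmos_anova"
  )
}

#' @export
print.gaitmos_anova <- function(x, ...) {
  cat("Factorial ANOVA on the margin of stability (Type II SS), ",
      if (x$aggregate) "subject" else "trial", "-level, n = ", x$n,
      "\n", sep = "")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Jeffreys-Zellner-Siow Bayes factor for paired differences
#'
#' Computes the default one-sample (paired) Bayes factor comparing the null
#' hypothesis of no between-system difference against a Cauchy-distributed
#' standardised effect with scale `r`. Writing `t` for the one-sample t
#' statistic and `nu = n - 1`,
#' \deqn{BF_{10} = \frac{\int_0^\infty (1 + n g r^2)^{-1/2}
#'   \left(1 + \frac{t^2}{\nu (1 + n g r^2)}\right)^{-(\nu+1)/2}
#'   \pi(g)\, dg}{\left(1 + t^2/\nu\right)^{-(\nu+1)/2}}}
#' with \eqn{\pi(g)} the inverse-gamma(1/2, 1/2) mixing density that makes
#' the effect-size prior a Cauchy with scale `r`. The integral is evaluated
#' by adaptive quadrature to a relative tolerance of 1e-8, and `BF01 =
#' 1 / BF10`. Values of BF01 above 3 are conventionally read as moderate
#' evidence that the two systems agree.
#'
#' The result carries BF01 at the three conventional prior scales —
#' 1/sqrt(2) ("user"), 1 ("wide") and sqrt(2) ("ultrawide") — and a
#' robustness curve over a log-spaced grid of scales.
#'
#' @param differences Numeric vector of paired differences (e.g. trial-level
#'   `MoS_FPS - MoS_MLS`).
#' @param prior_scale Cauchy prior scale r (default `1/sqrt(2)`).
#' @param r_grid Prior scales for the robustness curve.
#' @return An object of class `gaitmos_bf`: `t`, `n`, `prior_scale`, `bf01`,
#'   `bf10`, a `scales` tibble at the three conventional r values, and a
#'   `robustness` tibble (`r`, `bf01`).
#' @export
jzs_bf01 <- function(differences, prior_scale = 1 / sqrt(2),
                     r_grid = 10^seq(log10(0.01), log10(2), length.out = 40)) {
  x <- differences[!is.na(differences)]
  n <- length(x)
  if (n < 2) stop("need at least 2 paired differences", call. = FALSE)
  if (!(prior_scale > 0)) stop("prior scale must be positive", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    t <- if (mean(x) == 0) 0 else Inf
  } else {
    t <- mean(x) / (s / sqrt(n))
  }
  conventional <- c(user = 1 / sqrt(2), wide = 1, ultrawide = sqrt(2))
  res <- structure(
    list(
      t = t, n = n, prior_scale = prior_scale,
      bf10 = bf10_jzs(t, n, prior_scale),
      bf01 = 1 / bf10_jzs(t, n, prior_scale),
      scales = tibble::tibble(
        prior = names(conventional),
        r = unname(conventional),
        bf01 = vapply(conventional, function(r) 1 / bf10_jzs(t, n, r), 0)
      ),
      robustness = tibble::tibble(
        r = r_grid,
        bf01 = vapply(r_grid, function(r) 1 / bf10_jzs(t, n, r), 0)
      )
    ),
    class = "gaitmos_bf"
  )
  res
}

#' JZS Bayes factor BF10 for a given t statistic
#'
#' Lower-level quadrature kernel used by [jzs_bf01()]; exposed for checking
#' against independent implementations.
#'
#' @param t One-sample t statistic.
#' @param n Sample size.
#' @param r Cauchy prior scale.
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return BF10 (a positive number; `Inf` when `t` is infinite).
#' @export
bf10_jzs <- function(t, n, r, rel_tol = 1e-8) {
  stopifnot(n >= 2, r > 0)
  if (!is.finite(t)) return(Inf)
  nu <- n - 1
  log_h0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    q <- 1 + n * g * r^2
    exp(
      -0.5 * log(q) - (nu + 1) / 2 * log1p(t^2 / (nu * q)) -
        0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g) - log_h0
    )
  }
  # split at g = 1 (the mixing density's scale) to help the quadrature
  i1 <- stats::integrate(integrand, 0, 1, rel.tol = rel_tol,
                         subdivisions = 400L)
  i2 <- stats::integrate(integrand, 1, Inf, rel.tol = rel_tol,
                         subdivisions = 400L)
  i1$value + i2$value
}

#' @export
print.gaitmos_bf <- function(x, ...) {
  cat("JZS paired-samples Bayes factor, n = ", x$n, ", t = ",
      signif(x$t, 4), "\n", sep = "")
  cat("  BF01 = ", signif(x$bf01, 4), " at prior scale r = ",
      signif(x$prior_scale, 4), "\n", sep = "")
  sc <- x$scales
  cat("  conventional scales: ",
      paste(sprintf("%s (r = %.3f): %.3g", sc$prior, sc$r, sc$bf01),
            collapse = ";  "), "\n", sep = "")
  invisible(x)
}

#' Full between-system agreement report
#'
#' Runs the whole agreement battery on a paired MoS table: per-stratum
#' Bland-Altman summaries, the trial-level factorial ANOVA, and the JZS
#' Bayes factor on the pooled paired differences (with per-stratum
#' supplements). When `out_dir` is given, machine-readable CSV summaries
#' and the Bland-Altman / robustness figures are written there.
#'
#' @param mos_long Long MoS table from [compute_mos()] (both routes).
#' @param out_dir Optional output directory for CSV summaries and figures.
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return A list with elements `pairs`, `bland_altman`, `bland_altman_pooled`,
#'   `anova`, `bayes` (pooled), `bayes_by_stratum`.
#' @export
agreement_report <- function(mos_long, out_dir = NULL,
                             prior_scale = 1 / sqrt(2)) {
  if (is.null(mos_long) || nrow(mos_long) == 0) {
    stop("empty input", call. = FALSE)
  }
  pairs <- pair_mos(mos_long)
  ba <- bland_altman(pairs)
  ba_pooled <- bland_altman(pairs, by = character(0))
  aov_tab <- mos_anova(mos_long)
  bf <- jzs_bf01(pairs$diff, prior_scale = prior_scale)
  by_cols <- intersect(c("group", "condition"), names(pairs))
  bf_strata <- dplyr::summarise(
    dplyr::group_by(pairs, dplyr::across(dplyr::all_of(by_cols))),
    t = jzs_bf01(.data$diff, prior_scale)$t,
    bf01 = jzs_bf01(.data$diff, prior_scale)$bf01,
    .groups = "drop"
  )
  out <- list(pairs = pairs, bland_altman = ba,
              bland_altman_pooled = ba_pooled, anova = aov_tab, bayes = bf,
              bayes_by_stratum = bf_strata)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(ba, file.path(out_dir, "bland_altman.csv"))
    readr::write_csv(generics::tidy(aov_tab), file.path(out_dir, "anova.csv"))
    readr::write_csv(
      dplyr::bind_rows(
        dplyr::mutate(bf$scales, stratum = "pooled"),
        dplyr::mutate(bf_strata, prior = "user", r = prior_scale,
                      stratum = do.call(paste, c(bf_strata[by_cols],
                                                 sep = "/")))[,
          c("prior", "r", "bf01", "stratum")]
      ),
      file.path(out_dir, "bayes.csv")
    )
    ggplot2::ggsave(file.path(out_dir, "bland_altman.png"),
                    autoplot.gaitmos_ba(ba, pairs = pairs),
                    width = 9, height = 6, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "bf_robustness.png"),
                    plot_bf_robustness(bf), width = 6, height = 4,
                    dpi = 150)
  }
  out
}
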