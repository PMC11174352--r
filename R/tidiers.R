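#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the factorial ANOVA table
#'
#' @param x A `gaitmos_anova` object.
#' @param ... Ignored.
#' @return A tibble with one row per effect: `term`, `sumsq`, `df`,
#'   `statistic` (F), `p.value`.
#' @export
tidy.gaitmos_anova <- function(x, ...) {
  x$table
}

#' @rdname tidy.gaitmos_anova
#' @return `glance()` returns a one-row model summary (`r.squared`,
#'   `sigma`, `df.residual`, `nobs`).
#' @export
glance.gaitmos_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    nobs = x$n
  )
}

#' Tidy a Bayes-factor result
#'
#' @param x A `gaitmos_bf` object.
#' @param ... Ignored.
#' @return One row per conventional prior scale: `prior`, `r`, `bf01`,
#'   `bf10`, plus the shared `t` and `n`.
#' @export
tidy.gaitmos_bf <- function(x, ...) {
  dplyr::mutate(x$scales, bf10 = 1 / .data$bf01, t = x$t, n = x$n)
}

#' @rdname tidy.gaitmos_bf
#' @export
glance.gaitmos_bf <- function(x, ...) {
  tibble::tibble(t = x$t, n = x$n, prior_scale = x$prior_scale,
                 bf01 = x$bf01, bf10 = x$bf10)
}
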