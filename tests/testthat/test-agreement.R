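make_pairs <- function(d, base = 0.08) {
  tibble::tibble(
    diff = d,
    pair_mean = base + seq_along(d) * 1e-4,
    rel_diff = 100 * d / (base + seq_along(d) * 1e-4),
    rel_undefined = FALSE
  )
}

test_that("Bland-Altman summaries match hand computation", {
  d <- c(0.01, -0.01, 0.02, 0.00, -0.02)
  ba <- bland_altman(make_pairs(d), by = character(0))
  expect_equal(ba$n, 5)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$sd_diff, 0.0158, tolerance = 1e-3)
  expect_equal(ba$loa_lower, -1.96 * sd(d))
  expect_equal(ba$loa_upper, 1.96 * sd(d))

  # all differences zero: degenerate but well defined
  ba0 <- bland_altman(make_pairs(rep(0, 6)), by = character(0))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))

  # symmetric +d/-d differences: zero bias, limits at +/-1.96 SD
  ds <- rep(c(0.01, -0.01), 10)
  bas <- bland_altman(make_pairs(ds), by = character(0))
  expect_equal(bas$bias, 0)
  expect_equal(bas$loa_upper, 1.96 * sd(ds))
  expect_error(bland_altman(make_pairs(numeric(0))), "empty")
})

test_that("relative differences use the pair mean and flag zero-mean pairs", {
  pairs <- tibble::tibble(
    mos_fps = c(0.10, 0.02, 0.00),
    mos_mls = c(0.08, 0.02, 0.00)
  )
  long <- tibble::tibble(
    participant = rep("a", 6), trial = rep(1:3, 2),
    route = rep(c("FPS", "MLS"), each = 3),
    mos = c(pairs$mos_fps, pairs$mos_mls)
  )
  pm <- pair_mos(long)
  expect_equal(pm$diff, pairs$mos_fps - pairs$mos_mls)
  expect_equal(pm$rel_diff[1], 100 * 0.02 / 0.09)
  expect_true(pm$rel_undefined[3])
  expect_true(is.na(pm$rel_diff[3]))
})

test_that("LoA cover ~95% of large Gaussian samples", {
  set.seed(1234)
  d <- rnorm(1e5, mean = 0.002, sd = 0.01)
  ba <- bland_altman(tibble::tibble(diff = d, pair_mean = 0.08 + d / 2),
                     by = character(0))
  inside <- mean(d >= ba$loa_lower & d <= ba$loa_upper)
  expect_equal(inside, 0.95, tolerance = 0.005 / 0.95)
})

test_that("the factorial ANOVA reduces to classical results where it must", {
  # balanced two-group slice: F equals the squared pooled t statistic
  set.seed(11)
  df <- tibble::tibble(
    mos = c(rnorm(20, 0.08, 0.01), rnorm(20, 0.09, 0.01)),
    route = rep(c("FPS", "MLS"), each = 20),
    condition = "SVC",
    group = "YH"
  )
  fit <- stats::lm(mos ~ route, data = df)
  F_lm <- stats::anova(fit)[["F value"]][1]
  t2 <- stats::t.test(mos ~ route, data = df, var.equal = TRUE)$statistic^2
  expect_equal(F_lm, unname(t2))

  # full design: location invariance of every F statistic
  coh_mos <- tidyr::expand_grid(
    participant = sprintf("p%02d", 1:6),
    condition = c("SVC", "MVC"),
    trial = 1:3,
    route = c("FPS", "MLS")
  )
  set.seed(21)
  coh_mos$group <- rep(c("YH", "EH", "PD"), each = nrow(coh_mos) / 3)
  coh_mos$mos <- 0.08 + rnorm(nrow(coh_mos), 0, 0.01) +
    0.01 * (coh_mos$condition == "MVC")
  a1 <- tidy(mos_anova(coh_mos))
  coh_mos2 <- dplyr::mutate(coh_mos, mos = mos + 0.5)
  a2 <- tidy(mos_anova(coh_mos2))
  expect_equal(a1$statistic, a2$statistic)
  expect_equal(a1$p.value, a2$p.value)

  # Type II sums of squares equal the classical decomposition when balanced
  a_clas <- stats::anova(stats::lm(
    mos ~ system * velocity * group,
    data = dplyr::mutate(coh_mos, system = factor(route),
                         velocity = factor(condition),
                         group = factor(group))
  ))
  clas <- a_clas[["Sum Sq"]][match(a1$term, rownames(a_clas))]
  expect_equal(a1$sumsq, clas, tolerance = 1e-8)

  # degenerate input: all observations equal -> zero sums of squares
  a0 <- tidy(mos_anova(dplyr::mutate(coh_mos, mos = 0.08)))
  expect_equal(max(a0$sumsq[a0$term != "Residuals"]), 0, tolerance = 1e-20)
})

test_that("subject-aggregated ANOVA averages trials before fitting", {
  mos <- study_mos()[study_mos()$participant %in%
                       c("YH01", "YH02", "EH01", "EH02", "PD01", "PD02"), ]
  agg <- mos_anova(mos, aggregate = TRUE)
  expect_equal(agg$n, 6 * 2 * 2) # participants x conditions x systems
})

test_that("the JZS Bayes factor favours the null at t = 0 and is monotone in r", {
  for (n in c(10, 50, 330)) {
    bf <- jzs_bf01(rep(c(-1, 1), n / 2) * 0.01)
    expect_equal(bf$t, 0)
    expect_gt(bf$bf01, 1)
  }
  bf0 <- jzs_bf01(c(-0.01, 0.01, -0.01, 0.01, -0.01, 0.01))
  expect_true(all(diff(bf0$robustness$bf01) > 0))
})

test_that("quadrature matches an independent fixed-grid oracle", {
  for (t in c(0, 1, 2.5)) {
    for (n in c(10, 50, 330)) {
      for (r in c(1 / sqrt(2), 1, sqrt(2))) {
        expect_equal(bf10_jzs(t, n, r), bf10_oracle(t, n, r),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("the Bayes factor agrees with an independent reference implementation", {
  # reference values computed with an established Bayes-factor
  # implementation for the paired JZS t test
  expect_equal(bf10_jzs(2, 30, 1 / sqrt(2)), 1.1102318669692572,
               tolerance = 1e-6)
  expect_equal(bf10_jzs(2, 30, 1), 0.8761354077110212, tolerance = 1e-6)
  expect_equal(1 / bf10_jzs(0, 50, 1 / sqrt(2)), 6.500318745243149,
               tolerance = 1e-6)
  expect_equal(1 / bf10_jzs(1.5, 100, sqrt(2)), 5.8548751392855625,
               tolerance = 1e-6)
  expect_equal(bf10_jzs(3.2, 12, 1 / sqrt(2)), 6.783156400629743,
               tolerance = 1e-6)
})

test_that("degenerate difference vectors are handled explicitly", {
  # zero variance with a nonzero mean: evidence against the null is total
  bf <- jzs_bf01(rep(0.02, 10))
  expect_equal(bf$bf01, 0)
  expect_error(jzs_bf01(0.01), "at least 2")
  expect_error(jzs_bf01(rnorm(10), prior_scale = -1), "positive")
})

test_that("BF01 grows with n under a true null and vanishes under a true effect", {
  set.seed(99)
  null_small <- jzs_bf01(rnorm(20, 0, 0.01))$bf01
  null_large <- jzs_bf01(rnorm(2000, 0, 0.01))$bf01
  expect_gt(null_large, null_small)
  effect_large <- jzs_bf01(rnorm(2000, 0.01, 0.01))$bf01
  expect_lt(effect_large, 1e-6)
})

test_that("the agreement report bundles all statistics and writes its files", {
  mos <- study_mos()[study_mos()$participant %in%
                       c("YH01", "YH02", "EH01", "EH02", "PD01", "PD02"), ]
  dir <- withr::local_tempdir()
  rep <- agreement_report(mos, out_dir = dir)
  expect_s3_class(rep$bland_altman, "gaitmos_ba")
  expect_equal(nrow(rep$bland_altman), 6)
  expect_s3_class(rep$anova, "gaitmos_anova")
  expect_s3_class(rep$bayes, "gaitmos_bf")
  expect_equal(nrow(rep$bayes_by_stratum), 6)
  expect_true(all(file.exists(file.path(
    dir, c("bland_altman.csv", "anova.csv", "bayes.csv",
           "bland_altman.png", "bf_robustness.png")
  ))))
  expect_error(agreement_report(NULL), "empty")
})

test_that("tidiers and plots return the expected shapes", {
  mos <- study_mos()[study_mos()$participant %in% c("YH01", "EH01", "PD01"), ]
  pairs <- pair_mos(mos)
  ba <- bland_altman(pairs)
  p1 <- autoplot(ba, pairs = pairs)
  expect_s3_class(p1, "ggplot")
  bf <- jzs_bf01(pairs$diff)
  expect_s3_class(plot_bf_robustness(bf), "ggplot")
  expect_true(all(c("prior", "r", "bf01", "bf10") %in% names(tidy(bf))))
  expect_equal(nrow(glance(bf)), 1)
  av <- mos_anova(mos)
  expect_true(all(c("term", "sumsq", "statistic", "p.value") %in%
                    names(tidy(av))))
  expect_equal(glance(av)$nobs, nrow(mos))
  expect_s3_class(plot_trial_traces(noiseless_trial()), "ggplot")
})
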