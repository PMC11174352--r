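test_that("pendulum length and eigenfrequency follow their definitions", {
  expect_equal(pendulum_length(1.70), 0.97750)
  expect_equal(pendulum_length(1.00), 0.575)
  expect_equal(pendulum_length(2.00), 1.150)
  expect_error(pendulum_length(0), "positive")

  expect_equal(eigenfrequency(9.81), 1.0)
  expect_equal(eigenfrequency(1.0), sqrt(9.81), tolerance = 1e-10)
  expect_equal(eigenfrequency(0.97750), sqrt(9.81 / 0.9775),
               tolerance = 1e-10)
  expect_error(eigenfrequency(-1), "positive")
})

test_that("the extrapolated CoM and the MoS follow their definitions", {
  expect_equal(extrapolated_com(0.05, 0, 3), 0.05)
  expect_equal(extrapolated_com(0, 0, 3), 0)
  expect_equal(extrapolated_com(0.02, -0.15, 3.0), -0.03)
  expect_error(extrapolated_com(0, 0, 0), "positive")

  expect_equal(margin_of_stability(0.14, 0.05), 0.09)
  expect_equal(margin_of_stability(0.10, 0.10), 0)
  expect_equal(margin_of_stability(0.10, 0.12), -0.02)
  expect_error(margin_of_stability(-0.1, 0), "non-negative")
})

test_that("MoS is monotone in its components", {
  # larger base of support with a fixed extrapolated CoM: strictly safer
  bos <- seq(0.10, 0.18, by = 0.01)
  expect_true(all(diff(margin_of_stability(bos, 0.05)) > 0))
  # faster CoM motion toward the swing side: strictly less safe
  v <- seq(0, 0.3, by = 0.05)
  mos_v <- margin_of_stability(0.14, extrapolated_com(0.03, v, 3.17))
  expect_true(all(diff(mos_v) < 0))
})

test_that("event detection matches the constructed events on simulated trials", {
  for (s in 1:3) {
    tr <- simulate_trial(noiseless_profile(seed = s))
    ev <- detect_events(tr)
    tru <- truth_events(tr)
    expect_lte(abs(ev$foot_contact - tru$foot_contact), 1)
    expect_true(ev$onset < ev$foot_off && ev$foot_off < ev$foot_contact)
    # the kinematic contact rule agrees with the force rule within 2 samples
    ev_k <- detect_events(tr, source = "kinematic")
    expect_lte(abs(ev_k$foot_contact - ev$foot_contact), 2)
  }
})

test_that("a trial without a step raises a no-step error", {
  tr <- noiseless_trial()
  flat <- tr
  flat$forces <- dplyr::mutate(
    flat$forces,
    fz = ifelse(plate == 2, 0, fz),
    mx = ifelse(plate == 2, 0, mx)
  )
  # heel never lifts either
  flat$kinematics$heel_left_z <- 0 * flat$kinematics$heel_left_z
  expect_error(detect_events(flat), "no-step")
})

test_that("both measurement routes recover the analytic MoS on clean trials", {
  for (s in c(7, 21)) {
    tr <- simulate_trial(noiseless_profile(seed = s))
    ev <- detect_events(tr)
    fps <- mos_for_trial(tr, "fps", ev)
    mls <- mos_for_trial(tr, "mls", ev)
    expect_lt(abs(fps$mos - tr$truth$mos), 2e-3)
    expect_lt(abs(mls$mos - tr$truth$mos), 2e-3)
    expect_lt(abs(fps$mos - mls$mos), 2e-3)
  }
})

test_that("every MoS result satisfies the internal identities", {
  mos <- compute_mos(make_cohort(n_yh = 1, n_eh = 1, n_pd = 1,
                                 trials_per_condition = 1, seed = 9))
  expect_equal(mos$omega0, sqrt(9.81 / mos$l))
  expect_equal(mos$ycom_extrap, mos$ycom_fc + mos$vcom_fc / mos$omega0)
  expect_equal(mos$mos, mos$bos - mos$ycom_extrap)
  expect_equal(mos$stable, mos$mos > 0)
  expect_equal(mos$l, pendulum_length(mos$height))
})

test_that("the MoS is invariant under a shift of the laboratory frame", {
  tr <- noiseless_trial()
  shifted <- tr
  delta <- 0.37
  for (ch in c("com_y", "heel_left_y", "heel_right_y")) {
    shifted$kinematics[[ch]] <- shifted$kinematics[[ch]] + delta
  }
  shifted$meta$plate1_offset_y <- shifted$meta$plate1_offset_y + delta
  shifted$meta$plate2_offset_y <- shifted$meta$plate2_offset_y + delta
  ev <- detect_events(tr)
  for (route in c("fps", "mls")) {
    m0 <- mos_for_trial(tr, route, ev)
    m1 <- mos_for_trial(shifted, route, ev)
    expect_equal(m1$mos, m0$mos, tolerance = 1e-9)
    expect_equal(m1$ycom_extrap, m0$ycom_extrap, tolerance = 1e-9)
  }
})

test_that("a right-swing trial mirrors cleanly and still recovers the MoS", {
  tr <- simulate_trial(noiseless_profile(seed = 5, swing_side = "right"))
  ev <- detect_events(tr)
  fps <- mos_for_trial(tr, "fps", ev)
  mls <- mos_for_trial(tr, "mls", ev)
  expect_lt(abs(fps$mos - tr$truth$mos), 2e-3)
  expect_lt(abs(mls$mos - tr$truth$mos), 2e-3)
})

test_that("requesting the markerless route without kinematics names the channels", {
  tr <- noiseless_trial()
  ev <- truth_events(tr)
  tr$kinematics <- NULL
  expect_error(mos_for_trial(tr, "mls", ev), "com_y.*heel_left_y")
})

test_that("compute_mos returns one tidy row per trial and route", {
  coh <- make_cohort(n_yh = 1, n_eh = 1, n_pd = 1,
                     trials_per_condition = 2, seed = 4)
  mos <- compute_mos(coh)
  expect_equal(nrow(mos), nrow(coh) * 2)
  expect_setequal(unique(mos$route), c("FPS", "MLS"))
  expect_true(all(c("participant", "group", "condition", "trial",
                    "mos", "bos", "ycom_extrap", "stable") %in% names(mos)))
})
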