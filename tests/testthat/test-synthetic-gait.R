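test_that("noiseless channels satisfy Newton and inverted-pendulum consistency", {
  p <- noiseless_profile()
  tr <- simulate_trial(p)
  traj <- gaitmos:::ml_trajectory(p)
  f <- tidyr::pivot_wider(tr$forces, names_from = plate,
                          values_from = c(fx, fy, fz, mx, my, mz))
  tf <- f$time
  # F_y = m * a exactly on the stored force grid
  expect_equal(max(abs((f$fy_1 + f$fy_2) - p$mass * traj$a(tf))), 0,
               tolerance = 1e-12)
  # combined CoP = y - a / omega0^2 exactly (plate CoPs Fz-weighted)
  cop_chan <- ifelse(
    f$fz_2 > 10,
    (-f$mx_1 - f$mx_2) / (f$fz_1 + f$fz_2),
    -f$mx_1 / f$fz_1
  )
  cop_pred <- traj$y(tf) - traj$a(tf) / traj$omega0^2
  expect_lt(max(abs(cop_chan - cop_pred)), 1e-12)
  # quiet standing before onset: body weight on plate 1, none on plate 2
  pre <- tf < p$t_onset
  expect_equal(f$fz_1[pre], rep(p$mass * 9.81, sum(pre)))
  expect_equal(f$fz_2[pre], rep(0, sum(pre)))
})

test_that("ground truth matches the analytic margin-of-stability identity", {
  tr <- noiseless_trial()
  tru <- tr$truth
  # boundary-frame identity: the extrapolated-CoM coordinate is measured
  # from the stance-side boundary toward the swing side, and
  # MoS = BoS - YcoM
  expect_equal(tru$ycom_extrap,
               (tru$step_width / 2 - tru$stance_dir * tru$xcom_fc))
  expect_equal(tru$mos, tru$bos - tru$ycom_extrap)
  # analytic acceleration is the exact second derivative: spot-check by
  # Richardson central differences of the closed-form position
  p <- noiseless_profile()
  traj <- gaitmos:::ml_trajectory(p)
  ts <- c(0.3, 0.9, 1.3, 1.55)
  h <- 1e-5
  a_num <- (traj$y(ts + h) - 2 * traj$y(ts) + traj$y(ts - h)) / h^2
  expect_equal(traj$a(ts), a_num, tolerance = 1e-4)
})

test_that("default profile reproduces the reported gait-initiation magnitudes", {
  tr <- noiseless_trial()
  # ML base of support around 14 cm and extrapolated CoM around 5 cm from
  # the stance boundary at foot contact
  expect_equal(tr$truth$bos, 0.14, tolerance = 0.01)
  expect_equal(abs(tr$truth$ycom_extrap), 0.05, tolerance = 0.15)
})

test_that("simulation is bit-identical under a fixed seed", {
  p <- gait_profile(seed = 123)
  t1 <- simulate_trial(p)
  t2 <- simulate_trial(p)
  expect_identical(t1$forces, t2$forces)
  expect_identical(t1$kinematics, t2$kinematics)
  # and noise does change the channels
  t3 <- simulate_trial(gait_profile(seed = 124))
  expect_false(identical(t1$forces$fy, t3$forces$fy))
})

test_that("the ML CoM velocity peaks toward the stance side before foot-off", {
  for (s in 1:4) {
    p <- gait_profile(
      seed = s,
      com_peak_velocity = c(0.08, 0.1, 0.12, 0.15)[s],
      swing_duration = c(0.26, 0.3, 0.32, 0.34)[s]
    )
    traj <- gaitmos:::ml_trajectory(p)
    tt <- seq(0, traj$t_foot_contact, by = 1e-3)
    v <- traj$v(tt)
    expect_lt(tt[which.max(v)], traj$t_foot_off)
    expect_gt(max(v), 0) # toward the stance side
  }
})

test_that("invalid profiles are rejected", {
  expect_error(gait_profile(mass = -1), "mass")
  expect_error(gait_profile(kin_sd = -0.1), "noise SDs")
  expect_error(gait_profile(swing_duration = -0.2), "onset < foot-off")
  expect_error(gait_profile(com_excursion = 0.08, step_width = 0.14),
               "com_excursion")
})

test_that("cohorts are balanced by design and deterministic under seed", {
  small <- make_cohort(n_yh = 1, n_eh = 1, n_pd = 1,
                       trials_per_condition = 1, seed = 5)
  expect_equal(nrow(small), 6) # 3 groups x 2 conditions
  expect_setequal(unique(small$condition), c("SVC", "MVC"))
  expect_setequal(unique(small$group), c("YH", "EH", "PD"))

  again <- make_cohort(n_yh = 1, n_eh = 1, n_pd = 1,
                       trials_per_condition = 1, seed = 5)
  expect_identical(
    dplyr::select(small, -trial_data),
    dplyr::select(again, -trial_data)
  )
  expect_identical(small$trial_data[[3]]$forces, again$trial_data[[3]]$forces)
  expect_error(make_cohort(trials_per_condition = 0), "zero trials")
})

test_that("the default study cohort has 330 trials with plausible anthropometrics", {
  coh <- study_cohort()
  expect_equal(nrow(coh), (12 + 10 + 11) * 5 * 2)
  expect_equal(length(unique(coh$participant)), 33)
  expect_true(all(coh$mass > 30 & coh$mass < 130))
  expect_true(all(coh$height > 1.3 & coh$height < 2.1))
  # one anthropometric draw per participant, shared across that
  # participant's trials
  per <- dplyr::distinct(coh, participant, mass, height)
  expect_equal(nrow(per), 33)
})
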