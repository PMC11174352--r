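# Shared fixtures, built once per test run.

noiseless_profile <- function(seed = 7, ...) {
  gait_profile(seed = seed, force_sd = 0, moment_sd = 0, kin_sd = 0, ...)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

noiseless_trial <- function() {
  fixture("noiseless_trial", simulate_trial(noiseless_profile()))
}

# full-size study cohorts used by the acceptance checks (33 participants,
# 5 trials x 2 velocity conditions = 330 trials)
study_cohort <- function() {
  fixture("study_cohort", make_cohort(seed = 101))
}

study_mos <- function() {
  fixture("study_mos", compute_mos(study_cohort()))
}

biased_cohort <- function() {
  # markerless CoM shifted so that the markerless MoS is lowered by 0.02 m,
  # i.e. a +0.02 m force-plate-minus-markerless difference to be recovered
  fixture("biased_cohort", make_cohort(seed = 202, bias_mls = -0.02))
}

# independent fixed-grid quadrature oracle for the JZS Bayes factor:
# transform g = u / (1 - u) and trapezoid over 1e5 interior nodes
bf10_oracle <- function(t, n, r, nodes = 1e5) {
  nu <- n - 1
  u <- seq(1e-9, 1 - 1e-9, length.out = nodes)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  q <- 1 + n * g * r^2
  log_h0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  f <- exp(-0.5 * log(q) - (nu + 1) / 2 * log1p(t^2 / (nu * q)) -
             0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g) - log_h0) * jac
  pracma::trapz(u, f)
}
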