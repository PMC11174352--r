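Package: gaitmos
Title: Margin of Stability at Gait Initiation from Force-Plate and
    Markerless Motion-Capture Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the mediolateral margin of stability (MoS) at
    swing-foot contact during gait initiation from two independent
    measurement routes: centre-of-mass kinematics reconstructed from
    force-plate wrenches (Newton's second law with double trapezoidal
    integration, centre-of-pressure based base of support) and
    markerless motion-capture trajectories (backward finite-difference
    velocity, heel-to-heel base of support). Includes a synthetic
    gait-initiation generator with analytically known ground truth,
    zero-lag Butterworth filtering and resampling utilities, trial file
    I/O, and between-system agreement statistics: Bland-Altman limits of
    agreement, factorial ANOVA with Type II sums of squares, and the
    Jeffreys-Zellner-Siow Bayes factor for equivalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
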