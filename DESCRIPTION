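Package: gaitmode
Title: Gait-Mode Recognition from a Foot-Mounted IMU with a Tapped-Delay
    Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Continuous, causal recognition of walking gait modes (level
    ground, ascent, descent) from a single foot-mounted inertial
    measurement unit and two foot switches, for use with powered
    ankle-foot orthoses. Estimates vertical foot velocity by
    zero-velocity-update (ZUPT) corrected integration and foot pitch from
    orientation quaternions, classifies each sample with a small
    feed-forward neural network on tapped-delay inputs trained by
    Levenberg-Marquardt with Bayesian regularization, conditions the
    network output by first-order filtering and minimum-Bayes-risk
    Gaussian thresholding, and scores per-step success rate and detection
    delay in percent gait cycle. Includes a seeded synthetic gait
    simulator (stair and ramp protocols) so the whole pipeline is
    testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
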