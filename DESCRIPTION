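Package: peakswarm
Title: EEG Peak Detection with Particle-Swarm Feature Selection and
    Threshold Estimation
Version: 0.1.0
Authors@R:
    person("peakswarm", "maintainers", email = "peakswarm@example.org",
           role = c("aut", "cre"))
Description: Detects transient peaks in single-channel EEG-like signals
    using a three-point sliding-window candidate detector, a fourteen-feature
    time-domain peak catalogue (amplitudes, widths and slopes relative to
    valley, turning, half and moving-average-curve landmarks), and a
    conjunctive threshold rule classifier.  Feature selection and per-feature
    decision thresholds are estimated jointly by a hybrid binary/continuous
    particle swarm optimizer with a v-shaped transfer function and a
    geometric-mean fitness, in both synchronous and random-asynchronous
    update modes.  A seed-deterministic synthetic signal generator with
    planted transients and adversarial decoy events supports end-to-end
    parameter-recovery testing, and an experiment runner reproduces
    fixed-peak-model and feature-selection protocols over independent runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
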