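Package: cervgame
Title: Head-Tracking Serious Game Engine and Crossover Trial Tools for
    Cervical Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless implementation of an inertial-sensor-controlled
    serious game for task-oriented cervical exercise, together with the
    analysis tools of a crossover pilot trial of that intervention.
    Provides rotation algebra with YZX Euler decomposition, complementary
    filter fusion of gyroscope/accelerometer/magnetometer streams,
    neutral-pose calibration, absolute angular-to-screen mapping of head
    orientation to a cursor, target generation, hit detection and session
    scoring, a synthetic head-motion user simulator (with reaction delay,
    speed limits, motor noise and session-to-session learning) that also
    synthesizes the raw IMU signals, scorers for the SEQ, NDI and MMSE
    instruments, and crossover (AB/BA) trial analysis: paired t tests,
    Wilcoxon signed-rank by group, residual, period and sequence effects,
    and repeated-measures ANOVA over session scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
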