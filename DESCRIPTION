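Package: reflexvf
Title: Visual-Feedback Modulation of Wrist Stretch Reflexes: Simulation and
    Trial-Level Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse trial-based wrist-flexion
    experiments in which mechanical perturbations probe the short- and
    long-latency stretch reflex while visual feedback of the hand is rotated,
    mirror-reversed or eliminated, and sudden target jumps probe the reflexive
    visuomotor response.  Includes a seeded multi-participant trial generator
    (minimum-jerk kinematics, a second-order wrist plant driven by half-sine
    torque pulses, envelope-times-carrier surface EMG), zero-phase Butterworth
    preprocessing of kinematic and EMG signals, fixed-window reflex
    quantification with isometric normalization, successive-t-test response
    onset detection, the trial- and participant-level screening rules, and the
    inferential layer: repeated-measures ANOVA with partial eta squared and
    Tukey-HSD on the within-subject error term, paired t-tests with Cohen's d,
    and bootstrap confidence intervals for group-mean correlations between
    reflex gain and endpoint variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    emmeans
Config/testthat/edition: 3
LinkingTo:
    Rcpp
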