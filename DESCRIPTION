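Package: dualadapt
Title: Simulation and Kinematic Analysis of Dual Visuomotor Rotation Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying concurrent adaptation of reaching and pursuit
    tracking movements to opposing visuomotor rotations. Builds the trial
    schedules of three session designs (single reach training, single tracking
    training, and dual training with opposing +/-30 degree cursor rotations cued
    by movement type), generates synthetic 50 Hz hand/cursor/target trajectories
    from a contextual state-space learner (a shared adaptation state plus one
    state per movement type), and implements the full kinematic and learning
    analysis: low-pass Butterworth filtering, velocity-criterion movement onset
    and offset detection, angular error at peak velocity, pursuit tracking RMSE
    and latency descriptors, five-trial blocking, learning milestones, open-loop
    reach aftereffects, exponential learning-curve fits, and the associated
    ANOVA and t-test battery with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    minpack.lm,
    signal,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
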