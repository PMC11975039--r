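Package: vimreach
Title: Motor-Thalamic Spiking Analysis for 3D Center-Out Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analyzing single-unit spiking activity recorded from
    the cerebellar-receiving motor thalamus (VIM) while a subject performs a
    naturalistic 3D center-out-and-back reaching task. Provides reach-event
    detection from fingertip kinematics, fractional-interval firing-rate
    estimation, time-stretched peri-reach modulation testing against a
    Monte-Carlo shuffle baseline, Kruskal-Wallis directional tuning, lagged
    multiple linear regression of firing rates on kinematic and positional
    error features with a circular-shift null, exact Shapley decomposition
    of regression R-squared, and a synthetic-session generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
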