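Package: reachkin
Title: Kinematic Analysis of 3D Reach-to-Target Movements in Stroke Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting kinematic parameters from motion-capture
    recordings of three-dimensional reach-to-target movements and relating
    them to upper-extremity clinical outcome measures in stroke
    rehabilitation studies. Implements endpoint-marker metrics (movement
    time, trajectory directness, peak velocity and its timing, velocity-peak
    counting, log dimensionless jerk), marker-based joint-range and
    compensatory trunk-movement measures, and a statistical battery of
    Spearman correlation grids with Holm adjustment and Hinkle labels,
    bootstrapped paired t-tests with percentile confidence intervals,
    baseline-standardized Cohen's d, minimal clinically important difference
    (MCID) responder flags, and non-paretic reference bands. A
    minimum-jerk-based trial simulator with controllable submovement
    structure, path curvature, trunk compensation and marker noise provides
    fully ground-truthed synthetic cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
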