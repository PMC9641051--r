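Package: spinekinetics
Title: Moment-Rotation Kinetics for Spine Flexibility Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pure-moment flexibility tests of functional
    spinal units. Extracts the five standard kinetic measures from sampled
    moment-rotation curves: range of motion between the moment limits, the
    neutral zone bounded by local extrema of the second derivative of the
    smoothed curve, the neutral-zone stiffness, and the two elastic-zone
    stiffnesses fitted over the outer moment bands. Includes a parametric
    simulator that constructs moment-rotation curves (plus hysteresis loops
    and whole cohorts) with exactly known ground-truth measures,
    repeated-measures group statistics (Anderson-Darling, Levene,
    within-subjects ANOVA with Tukey post hoc, one-sample t), and an
    orchestration layer that runs simulate-extract-compare studies
    reproducibly from a seed.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
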