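Package: strikekin
Title: Feeding-Strike Kinematics from Markerless Landmark Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns 2-D landmark time series of salamander feeding strikes
    (DeepLabCut-dialect CSVs) into calibrated kinematic signals and a
    standard set of 32 strike variables (gape, hyoid, head-angle and tongue
    cycles), and runs the downstream statistical battery used in comparative
    feeding studies: permutation-based type II MANOVA with Pillai's trace,
    per-variable random-intercept mixed-model contrasts, correlation-matrix
    PCA with variable contributions, and group disparity with bootstrap and
    Wilcoxon tests. Includes a synthetic strike generator with closed-form
    ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    lme4,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
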