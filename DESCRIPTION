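Package: lapskill
Title: Motion-Capture Metrics and Skill Credentialing for Laparoscopic Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for objective assessment of laparoscopic surgical skill from
    instrument motion capture. Simulates two-handed instrument trajectories with
    controllable expertise effects, smooths tip tracks and estimates derivatives
    with a Savitzky-Golay filter, computes a suite of kinematic metrics
    (operative time, path length, velocity/acceleration/jerk, depth path length,
    working area, bimanual coordination, attitude angular lengths), screens
    metrics with Kruskal-Wallis and Mann-Whitney rank tests, summarizes them by
    principal component analysis, and discriminates experience levels with SVM,
    PCA-SVM and gradient-boosted decision trees under nested repeated k-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    e1071,
    xgboost,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
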