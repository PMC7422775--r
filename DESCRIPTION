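Package: complimetry
Title: Webcam Compliance Biomarkers and Compliance-Weighted Thresholding
    for Visual Field Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring task compliance during perimetry (visual
    field assessment) from webcam-derived facial features. Computes seven
    compliance biomarkers from gaze, head pose, facial action unit and
    response-latency streams (robust Sn dispersion statistics, mean action
    unit intensities, blink rate, mean latency) and a correlation-weighted
    composite; quantifies their association with test-retest measurement
    error in mean sensitivity and with trial-by-trial response lapses on
    suprathreshold stimuli; and implements Bayesian ZEST threshold
    estimation with optional per-trial compliance weighting of the
    likelihood. Includes a synthetic-session generator (latent two-state
    attention process driving gaze/head/expression emissions and response
    lapses) so the full pipeline can be exercised end to end with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
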