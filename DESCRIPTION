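Package: agreesim
Title: Simulation-Based Calibration of Inter-Evaluator Agreement Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relates inter-evaluator agreement (Krippendorff's alpha) to
    worst-case measurement error by injecting parameterized systematic and
    random Gaussian error into a reference dataset of ratio-scale
    measurements, summarizing the simulated evaluator population into
    agreement-error points, fitting a power-law worst-case error envelope,
    and deriving context-specific agreement thresholds for evaluator-based
    tests. Includes a coincidence-matrix Krippendorff's alpha implementation
    with ratio, interval and nominal difference functions, a seeded synthetic
    reference-dataset generator, percent-error metrics with subset-total
    aggregation, evaluator assessment against a fitted envelope, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
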