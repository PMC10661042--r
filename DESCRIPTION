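Package: delaygate
Title: Genetic Delay-Circuit Models and Plate-Reader Kinetics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Steady-state and dynamic models of transcriptional logic gates in
    relative promoter units (RPU), including Hill response functions, digital
    sensor gates, and first-order tau-ON/tau-OFF relaxation dynamics for a
    two-input genetic delay circuit.  Provides plate-reader time-series
    analytics (blank/OD normalization, detection time, fold change, hourly
    accumulated fluorescence, doubling time, lysis and rescue times, growth
    phase calling), multi-start Levenberg-Marquardt estimation of Hill and
    relaxation parameters with a staged parameter-fixing workflow that isolates
    the growth-phase-dependent gate turn-on rate, a four-parameter sigmoid
    trend model that predicts the turn-on rate at untested induction times, and
    a synthetic plate-reader data generator with recorded ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
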