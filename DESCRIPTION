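Package: causalphysio
Title: Granger and BPRSA Causality Analysis for Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify directed couplings between
    physiological time series such as heart rate, breathing rate and EEG
    alpha-band amplitude. Implements nested-autoregressive Granger
    causality (pairwise and conditional, with F and chi-squared tests),
    Bivariate Phase Rectified Signal Averaging (BPRSA) with four
    significance tests, an augmented Dickey-Fuller based recursive
    stationarity-splitting algorithm, coupled 1/f-noise benchmark systems
    with detection-limit and region-classification experiments, and a
    sleep-stage causal-network reconstruction pipeline with length-weighted
    averaging, bootstrap standard errors and inter-subject surrogate
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    readr,
    ggplot2,
    rlang,
    generics,
    withr,
    signal,
    nortest
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite,
    yaml
Config/testthat/edition: 3
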