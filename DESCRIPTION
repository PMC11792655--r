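Package: priomatch
Title: Behavioral and EEG Analysis of Friend- and Self-Prioritization in
    Shape-Label Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and characterizing friend-prioritization
    versus self-prioritization in the shape-label matching task. Provides a
    synthetic-data generator (forward drift-diffusion simulation of choices
    and reaction times, template-based EEG epochs with trial-coupled
    oscillations, trait and economic-game tables), response-efficiency
    classification of prioritization groups, signal detection theory indices,
    hierarchical Bayesian drift-diffusion model fitting with a Wiener
    first-passage-time likelihood, an outlier mixture and DIC model
    comparison, trial-by-trial neural-covariate regression onto decision
    parameters, ERP component extraction, Morlet wavelet time-frequency
    decomposition with ERS/ERD baseline normalization, cluster-based
    permutation statistics over time-by-electrode maps, and canonical
    correlation analysis with permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
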