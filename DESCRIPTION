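Package: carrionuse
Title: Two-Species Dynamic Occupancy Modelling of Winter Carrion Use
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates how two interacting fox species use ungulate carrion
    in winter from daily camera-trap detections. Converts photo records into
    filtered, week-segmented detection histories; builds geographic
    principal-component gradients, a feeding-station kernel density index
    and an annual rodent index; fits a four-state latent-Markov
    co-occurrence model with competitor- and resource-dependent colonization
    and extinction, imperfect daily detection and year random effects by
    MCMC over the marginalized (forward-algorithm) likelihood; derives
    stationary carrion-use probabilities from the weekly transition kernel;
    and runs chi-squared posterior predictive checks with Bayesian p-values.
    Includes a synthetic-data generator emulating the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    readr,
    lubridate,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
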