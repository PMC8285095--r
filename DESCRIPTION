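Package: pvlbayes
Title: Prospect Valence Learning Models of Iowa Gambling Task Decision
    Making with Hierarchical Bayesian Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes Iowa Gambling Task (IGT) choice behavior into
    decision-making component processes with the Prospect Valence Learning
    (PVL) family of reinforcement-learning models. Provides the canonical
    payoff environment and traditional IGT scores (net scores, deck
    proportions, block learning curves, polynomial trend contrasts), the
    four PVL variants (delta or decay expectancy updating crossed with
    trial-dependent or trial-independent softmax choice rules),
    hierarchical Bayesian estimation of subject- and group-level
    parameters by adaptive MCMC with Gelman-Rubin and Geweke diagnostics,
    model comparison by the deviance information criterion, Bayesian
    linear regression of outcomes on decision parameters that propagates
    full posterior uncertainty through a two-stage Gibbs scheme, the
    construction of substance-related health-risk outcome variables
    (harm-weighted use composites, risk-behavior counts, standardized
    indices, tertile frequency codes, EM imputation of questionnaire
    items), and a seeded synthetic cohort generator with known ground
    truth for end-to-end validation.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    truncnorm,
    utils
LinkingTo:
    Rcpp
Suggests:
    coda,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
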