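Package: funcresp
Title: Functional-Response Models for Predation Trials with Prey Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares predator functional-response models on
    predation-trial count data in which consumed prey are not replaced.
    Implements the Holling type II disc equation, the Rogers
    depletion-corrected (random-predator) type II model solved via the
    Lambert W function, a Hassell type III model with depletion, and the
    generalized flexible-exponent family that interpolates between type II
    and type III responses. Provides maximum-likelihood estimation under a
    binomial consumption likelihood, a polynomial-logistic shape test,
    AIC-based model selection, stratified nonparametric bootstrap
    confidence intervals, maximum feeding rates, a synthetic predation-trial
    generator replicating common arena designs (including alternative-prey
    and intraguild-predation treatments), and a config-driven analysis
    pipeline with tidy tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
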