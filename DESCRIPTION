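Package: mktraits
Title: Ancestral State Reconstruction and Correlated Evolution for Discrete Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the evolution of discrete morphological traits
    on time-calibrated phylogenies. Implements Sankoff parsimony with full
    most-parsimonious-reconstruction state sets, maximum-likelihood inference
    under the Mk model family (equal-rates, symmetric, all-rates-different,
    ordered and unidirectional variants) with small-sample AIC model selection
    and marginal ancestral state probabilities, and a reversible-jump Markov
    chain Monte Carlo sampler over rate-class partition models that integrates
    over posterior tree samples and reports credibility intervals for
    node-state probabilities. Pairwise correlated-evolution tests for binary
    characters combine maximum-likelihood Akaike weights over dependent and
    independent four-state models with a Bayes factor computed from
    reversible-jump model-visit frequencies. A synthetic-data module simulates
    ultrametric trees, discrete characters, correlated character pairs,
    missing-data patterns and pseudo-posterior tree sets so every stage of the
    pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
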