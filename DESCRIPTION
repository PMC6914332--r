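Package: glamr
Title: Gaze-Weighted Linear Accumulator Models for Multi-Alternative Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits and simulates the gaze-weighted linear accumulator model
    (GLAM), a linear stochastic race model of multi-alternative value-based
    choice in which evidence for an item accumulates at a discounted rate
    while the item is not fixated. Provides the closed-form inverse-Gaussian
    race likelihood over choices and response times, Bayesian parameter
    estimation for individual, pooled and hierarchical model variants
    (adaptive Metropolis MCMC and a mean-field variational approximation),
    WAIC/PSIS-LOO model comparison, posterior parameter contrasts between
    groups or conditions, forward simulation and posterior prediction of
    choice behaviour, behavioural summary statistics, and a command-line
    interface for the standard simulate/fit/predict/compare workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
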