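Package: ezbhddm
Title: EZ Bayesian Hierarchical Drift Diffusion Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Hierarchical Bayesian estimation of the three-parameter drift
    diffusion model through a proxy likelihood built from the sampling
    distributions of the EZ-diffusion summary statistics: the accuracy rate
    and the mean and variance of correct response times.  Provides a Wiener
    diffusion trial simulator, the closed-form forward and inverse EZ
    systems, binomial/normal/gamma sampling-distribution likelihoods, a
    population model with metaregression of a diffusion parameter on an
    external covariate, an adaptive Metropolis-within-Gibbs sampler with
    split R-hat and effective-sample-size diagnostics, Savage-Dickey Bayes
    factors for regression weights, parameter-recovery study harnesses, and
    CSV/JSON input-output with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
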