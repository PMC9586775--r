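Package: gedmix
Title: Bayesian Analysis of Right-Censored Two-Component Generalized
    Exponential Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling heterogeneous right-censored survival data
    with two-component mixtures of generalized exponential distributions
    (2CMGED) and their exponential special case (2CMED). Provides the
    censored mixture likelihood and maximum-likelihood fitting, Bayes
    estimation by Lindley's approximation and by importance sampling under
    squared-error, precautionary, entropy and LINEX losses with
    noninformative or Beta-Gamma informative priors, a censoring scheme that
    replaces censored items by conditional expectations of the residual
    lifetime, reliability characteristics (survival, hazard, reversed
    hazard), a Monte-Carlo simulation-study driver, and goodness-of-fit
    analysis of two bundled cancer-survival datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
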