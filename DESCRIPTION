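Package: blogitfe
Title: Fixed-Effects Binomial Logit Models for Panel Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Conditional maximum likelihood estimation of the fixed-effects
    binomial logit ("Blogit") model for bounded proportion outcomes in panel
    data, with the within-unit total as sufficient statistic for the
    individual effects.  Includes the dummy-variable and pooled binomial
    logit comparison estimators, a nonparametric test of the binomial
    (no-overdispersion) assumption in discrete-matching and kernel-weighted
    variants for two or more periods, simulators for binomial and
    beta-binomial panels with correlated individual effects, and a Monte
    Carlo harness for size, power and bias experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
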