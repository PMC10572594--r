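Package: bayesdx
Title: Bayesian Posterior Probability of Disease from Quantitative Diagnostic Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes Bayesian posterior probabilities of disease from one or
    two quantitative diagnostic tests. Class-conditional densities of the
    measurands in diseased and nondiseased populations are modelled either
    parametrically (normal, lognormal or gamma marginals, moment-matched to a
    user-supplied mean and standard deviation, joined by a Gaussian copula
    with correlation rho) or nonparametrically (univariate and bivariate
    Gaussian kernel density estimates with Silverman-based bandwidths).
    Includes goodness-of-fit diagnostics (Q-Q and P-P point sets, density
    histograms, descriptive statistics, log-likelihood), a synthetic cohort
    generator for right-skewed positively correlated paired measurands, and a
    command-line front end that emits posterior tables, curves, surfaces and
    their numeric twins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    e1071
Config/testthat/edition: 3
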