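Package: itvar
Title: Intraspecific Trait Variation and Environmental Heterogeneity
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intraspecific trait variation (ITV) of log-transformed
    functional traits with a sample-size (Bessel) correction, relates
    within-site ITV to site-level spatial and temporal environmental
    variability through a hierarchical Bayesian random-slopes model with
    sample-size-scaled residual error, and relates across-site ITV (or
    species mean traits) to the breadth of species' environmental
    distributions through Bayesian linear regression with AIC backward
    selection and variance-inflation diagnostics. Includes environmental
    variability metrics (terrain roughness index from gridded elevation,
    rainfall seasonality as the coefficient of variation of monthly
    precipitation), niche-breadth estimation from occurrence records, and a
    synthetic-data generator with saved ground truth so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
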