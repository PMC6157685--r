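Package: mejaglmm
Title: Bayesian GLMMs for Multiannual Induced-Defense Field Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for repeated-measures field experiments on
    induced plant defense, built around the bilberry (Vaccinium myrtillus)
    methyl jasmonate (MeJA) transect design. Provides a validated long-format
    census data model, a nondestructive allometric dry-mass estimator,
    means-parameterized generalized linear mixed models (Gaussian, binomial
    and Poisson with observation-level overdispersion and zero-inflation)
    fitted by MCMC through JAGS, Gelman-Rubin convergence and posterior-shape
    diagnostics, posterior-contrast significance tables for treatment-versus-
    control comparisons, and a synthetic-data generator with the full block/
    transect/distance-class structure for calibration and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: JAGS (>= 4.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
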