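Package: twinpath
Title: Twin-Design Variance Decomposition for Multivariate Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and maximum-likelihood analysis of classical twin
    designs. Generates synthetic twin cohorts with known additive-genetic (A),
    shared-environment (C) and nonshared-environment (E) structure across five
    zygosity groups; prepares phenotypes (composite scoring, age/sex
    residualization, one-twin-per-pair selection, descriptive screening); fits
    confirmatory factor models with standard fit indices (CFI, TLI, RMSEA,
    SRMR, AIC and Akaike weights); and fits univariate ACE models,
    five-group sex-limitation models, common pathway models, hierarchical
    second-order biometric models and Cholesky decompositions by
    full-information maximum likelihood, with profile-likelihood confidence
    intervals and path-tracing apportionment of genetic variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
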