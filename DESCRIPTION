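Package: acegrowth
Title: Genetic and Environmental Variance Decomposition of Height Across the Growth Period in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical twin design applied to height from infancy
    to early adulthood. Simulates multi-region twin-cohort height data with a
    known additive genetic / shared environmental / unique environmental (ACE)
    structure, reproduces the sample-construction and residualization steps of
    large pooled twin analyses, and estimates age-, sex- and region-specific
    variance components by maximum likelihood: a univariate ACE sex-limitation
    model per one-year age group (with saturated and nested submodels,
    likelihood-ratio tests, Bonferroni correction, and profile-likelihood
    confidence intervals), and a gene-by-age interaction model in which path
    coefficients are quadratic functions of age.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
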