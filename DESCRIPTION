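Package: phenodiv
Title: Phenotypic Diversity and Quantitative-Genetic Evaluation of
    Multi-Year Variety Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating germplasm collections and breeding
    populations from multi-year randomized complete block trials.
    Implements Shannon-Weaver phenotypic diversity indices with
    within/between-region partitioning on five-class trait binning,
    expected-mean-squares variance-component estimation with
    broad-sense heritability and genotypic/phenotypic coefficients of
    variation, predicted response to truncation selection and genetic
    gain, genotypic and phenotypic trait correlations from covariance
    components, principal component analysis with Ward clustering of
    genotype means, and superior-genotype screening against parental
    checks. A multi-environment trial simulator with known ground-truth
    variance components and genetic correlations supports
    parameter-recovery validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
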