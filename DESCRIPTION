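Package: propcoloc
Title: Proportional Colocalisation Testing for Genetic Association Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether two traits, measured in distinct cohorts, share a
    common causal variant within a genomic region by testing proportionality
    of joint regression coefficients. Implements the Fieller-statistic
    profile test and Bayesian posterior-predictive p-values, with two
    unbiased SNP-summarisation strategies (principal components of the
    combined genotype matrix, and Bayesian model averaging over two- or
    three-SNP models weighted by BIC-approximated posteriors), alongside the
    biased selection strategies they replace (conditional testing, top-SNP
    pairs, lasso selection). A haplotype simulation engine generates
    block-LD panels, case-control samples under a multiplicative risk
    model, and quantitative traits for type-1-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
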