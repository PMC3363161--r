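Package: gpqtl
Title: Genomic Prediction and QTL Mapping with Bayesian Whole-Genome
    Regression and GBLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-generation full-sib populations with linked SNP
    genotypes by gene dropping and a known quantitative-trait architecture
    (additive, imprinted and additive-by-additive epistatic QTL), and analyses
    them with single-site Gibbs samplers for BayesB and BayesCpi (including a
    joint additive-plus-dominance model), GBLUP with additive, dominance and
    epistatic genomic relationship matrices estimated by average-information
    REML, backsolving of allele substitution effects from genomic breeding
    values, and QTL localization from 10-SNP window variances and posterior
    inclusion probabilities. Includes evaluation utilities (validation
    accuracy, method correlations, detection tables) and tidy/ggplot2 methods
    for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
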