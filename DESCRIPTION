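Package: pcreml
Title: Average-Information REML for Multivariate Animal Models with
    Pedigree, Genomic and Single-Step Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Restricted maximum likelihood (REML) estimation of genetic and
    residual covariance matrices for multivariate animal models via the
    average-information (AI) algorithm.  Supports the standard multivariate
    parameterisation and the equivalent principal-components parameterisation
    in which genetic effects are rescaled to unit variance so that the
    relationship part of the mixed-model equations becomes a Kronecker
    product with an identity matrix, dramatically sparsifying the coefficient
    matrix when dense (genomic or single-step) relationship matrices are
    used.  Includes construction of the inverse numerator relationship matrix
    by Henderson's rules with exact inbreeding, VanRaden Method 1 genomic
    relationship matrices, single-step H-inverse assembly, sparse Cholesky
    factorisation with a Takahashi-type sparse inverse subset, a synthetic
    data generator (generation-structured pedigrees, gene-dropped SNP
    genotypes, multivariate phenotypes with partial genotyping), and dense
    brute-force oracles for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
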