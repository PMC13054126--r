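Package: feedlotgen
Title: Genetic Analysis of Feedlot Profitability Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving economic feedlot phenotypes (accumulated
    feedlot profitability and profit per arroba of carcass gain) and
    auxiliary performance traits (residual feed intake, residual gain,
    frame score, age-adjusted weight) from daily feedlot records,
    editing phenotypes into contemporary groups, building pedigree,
    genomic and single-step relationship matrices, and estimating
    variance components, heritabilities and genetic correlations with a
    multi-trait Bayesian linear-threshold animal model fitted by Gibbs
    sampling. A synthetic-data generator reproduces the statistical
    structure the model assumes (multi-generation pedigrees, gene-dropped
    genotypes, breeding values with Mendelian sampling, liability-scale
    binary traits and feedlot sensor logs) so the whole pipeline can be
    exercised and validated without proprietary herd data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, methods, Matrix, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
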