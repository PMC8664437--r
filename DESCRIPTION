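Package: bulkscan
Title: Fast Bulk eQTL Genome Scans by Matrix Multiplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide expression QTL (eQTL) scans for two-genotype-class
    populations such as recombinant inbred panels. One-degree-of-freedom
    Haley-Knott LOD scores for every trait-by-marker pair are obtained as an
    element-wise transform of the Pearson correlation matrix, itself computed
    as a single cross-product of column-standardized trait and genotype
    matrices. Covariates are handled by orthogonal projection (residualization)
    of both traits and genotypes before standardization. Includes a
    GeneNetwork-style '.geno' reader, minor-allele-frequency filtering,
    per-trait maximum-LOD peak reduction with trait chunking, an optional
    single-precision compute path, a brute-force nested-regression oracle for
    verification, a recombinant-inbred panel simulator with planted eQTL, a
    trans-eQTL map plot, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
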