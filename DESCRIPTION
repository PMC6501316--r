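Package: scBulkImpute
Title: Bulk-Constrained Low-Rank Imputation of Single-Cell RNA-seq Dropouts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes dropout zeros in single-cell RNA-seq expression
    matrices by non-negative, low-rank (nuclear-norm regularised) matrix
    completion constrained to agree with matched bulk RNA-seq averages.
    The convex objective is solved by an alternating direction method of
    multipliers (ADMM) with singular value thresholding; the per-iteration
    X-subproblem is solved exactly by projected Gauss-Seidel sweeps
    implemented in C++. The package also ships a cluster-structured
    dropout-data simulator (Gaussian perturbation of per-cluster gene
    means followed by gene-wise Bernoulli dropout at rate
    exp(-lambda * mean^2)), evaluation statistics (imputation error,
    Kolmogorov-Smirnov distribution agreement, correlation-structure
    preservation, cluster-stratified distortion, pathway gene correlation
    scores, Dunn index), file readers and writers for dense and Matrix
    Market expression formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
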