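Package: pathscore
Title: Single-Sample Pathway Analysis and Semi-Synthetic Benchmarking for
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Pathway", "Maintainer", email = "maintainer@pathscore.dev",
           role = c("aut", "cre"))
Description: Transforms a samples-by-metabolites abundance matrix into a
    samples-by-pathways score matrix using six single-sample pathway
    analysis (ssPA) algorithms: z-score, SVD (PLAGE), ssGSEA, GSVA,
    ssClustPA (k-means projection) and kPCA (RBF kernel PCA). Includes
    readers for GMT and Reactome ChEBI pathway collections, the
    Szymkiewicz-Simpson overlap coefficient and greedy non-redundant set
    construction, a metabolomics post-processing chain (iterative-SVD
    imputation, probabilistic quotient normalisation, log2 transform,
    standardisation), conventional ORA and permutation-GSEA comparators,
    a semi-synthetic "permute-and-spike" benchmarking engine with an
    overlap-coefficient truth model and recall/precision/AUC metrics,
    synthetic data generators, and downstream clustering and pathway
    correlation-network analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
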