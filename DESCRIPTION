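Package: stapp
Title: Stability-Driven NMF and Atlas Linking for 3D Spatial Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised discovery of stable principal patterns (PPs) in
    stacks of 3D spatial gene expression volumes, and their linking to a
    labeled anatomical atlas. Provides k-nearest-neighbour voxel imputation,
    non-negative matrix factorization by coordinate descent with
    deterministic initialization, bootstrap stability analysis for model
    selection (Hungarian-matched and Amari-type dictionary dissimilarities),
    global Moran's I spatial coherence scoring, morphological region
    adjacency queries, maximal-correlation linking of patterns to single
    regions and contiguous pairs and triples of regions, marker-gene
    importance ranking, spatial gene coexpression networks, and a
    planted-factor synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    glmnet,
    igraph,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
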