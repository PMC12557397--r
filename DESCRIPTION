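Package: pathsep
Title: Pathway Separation of Biased Ligand Unbinding Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies ensembles of biased protein-ligand unbinding
    trajectories into pathways. Trajectories are represented by
    ligand-protein contact distances, optionally smoothed, normalized and
    reduced by contact principal component analysis, and compared pairwise
    with four similarity measures (mean Euclidean distance, dependent
    dynamic time warping, Procrustes disparity, summed one-dimensional
    Wasserstein distance). The resulting similarity matrix is clustered by
    Leiden community detection under the Constant Potts Model with
    quantile-based resolution selection, clusterings are scored against
    ground truth with normalized mutual information, and per-pathway free
    energy profiles are estimated from nonequilibrium work curves via the
    second-order cumulant expansion of the Jarzynski equality
    (dissipation-corrected targeted MD). A synthetic ensemble generator
    emulating constraint and restraint pulling provides ground-truth
    labeled test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
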