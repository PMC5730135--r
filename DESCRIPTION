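Package: dispquant
Title: Area-Based Quantification of Hard- and Soft-Tissue Displacement
    Between Superimposed 3D Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional hard- and soft-tissue displacement
    between two rigidly superimposed scans of the same subject, the way
    orthognathic-surgery outcome studies measure it: cranial-base voxel-based
    rigid registration by mutual information, label-separated isosurface
    extraction to triangle meshes, operator-painted surface regions, and
    signed region-restricted closest-point displacement statistics
    (minimum, maximum, mean). Includes a synthetic two-time-point phantom
    generator with known per-label rigid transforms and a statistically
    coupled soft-tissue shell, plus the accompanying reliability
    (intraclass correlation) and hard-to-soft Spearman correlation analysis
    with exact permutation p-values at small sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    digest,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
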