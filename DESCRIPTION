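Package: kinclust
Title: Digital-Biopsy Voxel Network Clustering for Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven analysis of dynamic positron emission
    tomography (PET), built around a digital-biopsy workflow: standardized
    300-voxel volumes of interest are sampled from 4D activity images,
    voxelwise time-activity curves are correlated into a Pearson network,
    reduced by k-nearest-neighbour edge filtering, and partitioned with
    Markov clustering.  Cluster-level readouts (purity, clusters per volume
    of interest, averaged cluster kinetics, coclustering) separate tissue
    classes by their tracer kinetics, for example slow-washout malignant
    from fast-washout inflammatory pancreatic lesions imaged with
    fibroblast-activation-protein inhibitor (FAPI) ligands.  A ground-truthed
    synthetic dynamic-PET phantom generator with configurable tissue kinetics
    supports validation and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
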