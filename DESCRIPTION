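Package: fabelast
Title: Fabric-Elasticity Analysis of Trabecular Bone Micro-CT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of trabecular bone regions of interest:
    preprocessing of grey-value micro-CT volumes (ROI selection, block
    coarsening, Otsu segmentation, island cleaning), standard 3-D
    morphometry with the mean-intercept-length fabric tensor, voxel
    micro-finite-element homogenization of the apparent stiffness under
    kinematic uniform boundary conditions, log-space regression of the
    Zysset-Curnier fabric-elasticity model, and two-group cohort
    comparison with density/anisotropy matching. Includes synthetic
    structure and cohort generators so the full pipeline is testable
    without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
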