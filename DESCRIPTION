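Package: nucleomorph3d
Title: Automated 3D Nuclear Morphometry of Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Volumetric single-cell image analysis for isotropic 3D nuclear
    morphometry. Provides a synthetic phantom generator for H&E-like stained
    single cells with full ground truth, segmentation of cell, nucleus,
    nucleoli and chromatin condensation states, a canonical set of 42
    morphological and textural descriptors (including 3D gray-level
    co-occurrence texture over the 26-voxel neighbourhood at multiple length
    scales), four-category nuclear shape classification, and multi-group
    feature screening (Shapiro-Wilk gated ANOVA/Kruskal-Wallis with
    Scheffe-corrected pairwise contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
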