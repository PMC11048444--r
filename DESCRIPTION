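Package: hpca
Title: Multiresolution Hierarchical Principal Component Analysis for
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treelet-style hierarchical principal component analysis (hPCA)
    for multiresolution functional-connectivity analysis of voxel-by-time
    data. Builds a full merge hierarchy from iterated two-variable local
    PCAs with signed correlation as the similarity measure, filters the
    resulting levels with a parametric Smallest Eigenvalue Test and a
    one-tailed correlation test under Bonferroni family-wise error control,
    and back-reconstructs subject-specific time series and z-scored spatial
    maps through a two-stage (subject and group) PCA compression with
    temporal concatenation. Includes a hierarchical network simulator for
    fMRI-like data (nested block spatial hierarchies, Bernoulli neural
    events convolved with a double-gamma haemodynamic response, Rician
    scanner noise) and an evaluation harness with a FastICA baseline for
    accuracy comparisons against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    RNifti,
    optparse
Config/testthat/edition: 3
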