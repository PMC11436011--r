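Package: seedscan
Type: Package
Title: Automated 3D Seed Phenotyping from Batch Point-Cloud Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@seedscan.dev",
    role = c("aut", "cre"))
Description: Turns batch table-top 3D scans of seeds into watertight
    single-seed models and quantitative phenotypes. Implements RANSAC plane
    removal and region-growing segmentation of individual seeds,
    covariance-eigenvalue dimensionality filtering, PCA pose normalization,
    completion of the unscanned bottom face by slab-wise constrained
    least-squares ellipse fitting (4ac - b^2 = 1), star-shaped surface
    reconstruction, 33 size- and shape-related traits, and PCA-based
    composite shape models with normalized per-trait weights. A synthetic
    seed and table-scene generator emulates scanner output so the full
    pipeline can be exercised and validated without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, jsonlite, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
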