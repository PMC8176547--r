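Package: leafgrid
Title: Grid-Division Deep-Feature Fusion for Leaf Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classifies single-leaf plant images by species using a
    multi-division feature-fusion pipeline: background cropping by
    thresholding and morphology, division of each image into an n x n grid
    of tiles, per-tile deep-feature extraction through a pluggable backbone
    contract, per-tile principal-component selection, feature fusion with
    z-score normalization, and a one-vs-all quadratic-kernel support vector
    machine evaluated by stratified k-fold cross-validation. Includes a
    deterministic synthetic leaf-image generator with ground-truth masks so
    every stage is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Classification, FeatureExtraction, Preprocessing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classify.R'
    'features.R'
    'leafgrid-package.R'
    'pipeline.R'
    'reduce-fuse.R'
    'segmentation.R'
    'synthetic.R'
    'tiling.R'
    'utils.R'
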