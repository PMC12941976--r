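Package: xaibench3d
Title: Cross-Domain Benchmarking of Attribution Maps for 3D Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified framework for generating and quantitatively evaluating
    explanations of 3D deep classifiers across volumetric scans, binary
    occupancy voxel grids, and point clouds. Implements post hoc attribution
    (Grad-CAM for grids and point clouds, input-gradient saliency, integrated
    gradients, occlusion sensitivity) and intrinsic attention extraction
    behind a model-adapter contract; perturbation-based faithfulness metrics
    (area over the perturbation curve, area under the preservation curve)
    and spatial compactness at fixed and adaptive thresholds; and a
    nonparametric comparison layer (Kruskal-Wallis with eta-squared,
    Mann-Whitney U with exact permutation p-values, Bonferroni correction,
    Cohen's r, interquartile-range outlier filtering). Ships deterministic
    synthetic generators for all three modalities with known class-relevant
    regions, plus tiny closed-form model fixtures, so the full benchmark
    protocol runs end to end without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
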