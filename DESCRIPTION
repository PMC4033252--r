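Package: corthick
Title: Laplacian Streamline Cortical Thickness and Patch-Based Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, testable pipeline for surface-based cortical
    morphometry: cortical thickness estimation by solving Laplace's equation
    between the white-matter and pial boundaries and tracing streamlines of
    the harmonic potential; geodesic-style smoothing of per-vertex maps on
    triangulated meshes; vertex-wise two-sample statistics with
    permutation-based cluster-level multiple-comparison control; patch-based
    dimensionality reduction by spatial k-means subdivision of anatomical
    labels; and class-imbalance-aware support-vector-machine evaluation under
    repeated stratified holdout with ROC vertical averaging. Includes a
    synthetic-data module (analytic phantoms and simulated cohorts) so every
    stage is validated without access to any clinical dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    e1071,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
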