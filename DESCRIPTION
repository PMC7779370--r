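Package: connharm
Title: Connectome Harmonics and Their Robustness to Structural Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds high-resolution gray + white matter structural connectomes
    from a triangulated cortical surface mesh and tractography streamlines,
    computes connectome harmonics (graph-Laplacian eigenmodes), and quantifies
    their robustness to connectivity alterations: weight thresholding,
    length-based trimming, callosectomy, local-edge anisotropy, mesh smoothing,
    and degree-preserving randomization null models. Similarity between
    harmonics and binary resting-state network maps is measured by mutual
    information with Monte-Carlo surrogate statistics. A synthetic two-sphere
    brain generator provides meshes, streamline sets, parcellations, and
    planted network maps with analytic spherical-harmonic references for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    pracma,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
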