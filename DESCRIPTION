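Package: mecmap
Title: Spatial Coding and Remapping Analysis for Entorhinal Recordings in Virtual Reality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-unit recordings from the medial
    entorhinal cortex of mice running on circular virtual-reality tracks.
    Provides per-cell spatial tuning metrics (coherence, sparsity,
    information), dark-running distance tuning and grid-scale estimation
    via autocorrelation peaks with spike-time shuffle nulls, speed tuning
    and stability scores, shuffle-based functional cell typing, cross-trial
    similarity and context-remapping statistics, factorized k-means
    clustering of trial-by-trial population spatial maps with silhouette
    model selection and speckled-holdout cross-validation, circular-linear
    position decoding, and LFP band-power estimation. A seeded synthetic
    session generator produces behavior and inhomogeneous-Poisson spike
    trains with ground truth so every stage can be validated without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
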