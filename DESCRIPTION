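Package: moabench
Title: Benchmarking Mechanism-of-Action Prediction from High-Content Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for comparing image modalities and feature representations
    for mechanism-of-action (MoA) prediction in high-content screening.
    Provides a synthetic screen generator with realistic plate, replicate and
    batch-effect structure (brightfield z-stacks and fluorescence channel
    stacks plus engineered feature tables), background correction and the two
    plate-level normalization strategies used in morphological profiling,
    compound-stratified data splitting, small multi-channel convolutional and
    feed-forward classifiers with penultimate-layer feature extraction,
    classification metrics (macro-F1, per-class F1, compound-level accuracy
    and cross-modality agreement), the grit replicate-strength score,
    regularized sphering (whitening) of control-well profiles, cosine-ranked
    mean average precision for biological matching, and plate-effect
    diagnostics. An orchestration layer ties the stages into reproducible
    end-to-end runs on synthetic data at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    ggplot2
Config/testthat/edition: 3
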