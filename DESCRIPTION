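Package: sgpred
Title: Prediction of Heat-Stress Recruitment of Prion-Like Domains to Stress Granules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a prion-like domain (PrLD) is recruited into
    stress granules upon heat stress from three sequence-derived biophysical
    features: a sliding-window aggregation-propensity score (Na4vSS),
    the net charge per residue at a given pH (Henderson-Hasselbalch), and the
    cysteine percentage. The three features feed a small feed-forward neural
    network (3-9-6-1, hyperbolic-tangent units) trained by batch gradient
    descent with momentum and an adaptive learning rate. Includes FASTA input
    and output, labeled-dataset handling, a seeded synthetic PrLD generator
    with class-specific residue compositions, full binary-classification
    evaluation (confusion counts, six performance metrics, ROC/AUC,
    two-tailed Mann-Whitney test, stratified splitting), model serialization
    to JSON, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
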