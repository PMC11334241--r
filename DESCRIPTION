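Package: siamquality
Title: Quality-Paired Self-Supervised Contrastive Learning for PPG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised contrastive pretraining for photoplethysmography
    (PPG) signals that pairs high-quality segments with temporally adjacent
    low-quality segments from the same patient, trains a SimSiam-style siamese
    network (1-D residual convolutional encoder, projector, predictor, negative
    cosine loss with stop-gradient) under curriculum ordering by artifact-level
    difference, and evaluates robustness with the Artifact-Tolerance curve.
    Includes a PPG simulator with labelled artifacts, a 30-second segmentation
    and normalization pipeline, a heuristic signal-quality estimator, fine-tuning
    strategies for downstream regression and classification, manifest-based I/O
    (CSV and minimal WFDB), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
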