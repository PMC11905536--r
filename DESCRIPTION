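Package: methylosr
Title: Open-Set Classification of DNA Methylation Array Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An imbalance-aware, open-set classification pipeline for CNS
    tumour DNA-methylation array profiles. Beta-value matrices are probe
    filtered, log2-transformed and batch corrected with a per-probe linear
    model; class imbalance is addressed with SMOTE oversampling; probes are
    ranked by random-forest impurity importance; a single-hidden-layer
    perceptron with leaky-ReLU activation is trained on the selected panel;
    and SoftMax outputs are recalibrated with per-class Weibull tail models
    (OpenMax) so that atypical samples can be assigned to an explicit
    "unknown" class. Includes a 92-label micro/macro-F1 evaluation
    protocol with an unknown label, a noise-injection experiment, a
    calibrated-score decision framework, a t-SNE embedding for visual
    inspection, and a seeded simulator of Infinium-like beta-value cohorts
    with class imbalance, batch effects and held-out novel classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    fitdistrplus,
    jsonlite,
    limma,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
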