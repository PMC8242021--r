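Package: dpsgd
Title: Differentially Private Training with Per-Sample Gradients and
    Gaussian Differential Privacy Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differentially private stochastic gradient descent (DP-SGD) for
    image classification and segmentation models, built around exact
    per-sample gradients obtained from weight-sharing model replicas.
    Provides per-sample gradient clipping and calibrated Gaussian noising,
    privacy accounting under the Gaussian Differential Privacy (GDP) central
    limit composition for Poisson and uniform subsampling as well as an
    integer-order Renyi Differential Privacy (RDP) accountant, automatic
    training interruption when the privacy budget is exhausted, model surgery
    that detects and repairs layers incompatible with per-sample gradient
    semantics (batch-normalisation running statistics), cryptographically
    secure Gaussian noise generation, privacy-aware data loading (uniform and
    Poisson minibatch sampling, occurrence counting), and seeded synthetic
    classification and segmentation image generators for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
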