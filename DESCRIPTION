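Package: fedlorasim
Title: Federated Low-Rank Adaptation of Vision Transformers, Simulated
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale simulator for communication-efficient federated
    fine-tuning of a DeiT-tiny Vision Transformer on binary chest-radiograph
    classification. Clients holding non-IID (Dirichlet label-skewed) shards
    train LoRA adapters under the FedProx proximal objective; a server
    aggregates updates by sample-weighted averaging and accounts for the
    exact per-round communication payload. Includes exact parameter
    accounting, a synthetic chest-X-ray generator, classification metrics
    with ROC/PR analysis and Youden-J thresholding, and attention-rollout
    and RISE saliency heatmaps. The transformer forward pass and its
    reverse-mode gradients are implemented in base R matrix code and
    verified against numerical differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    optparse
Config/testthat/edition: 3
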