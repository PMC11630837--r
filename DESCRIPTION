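Package: drugrank
Title: Drug Repositioning by Graph-Contrastive Pretraining and Ranking Fine-Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for computational drug repositioning on a drug-disease
    heterogeneous graph. Node features are built from expression-perturbation
    signatures, embeddings are pretrained with model-augmented graph
    contrastive learning (edge dropping, feature masking, propagation-depth
    jitter), and a residual-like graph convolution network is fine-tuned with
    a Bayesian-weighted combination of a binary treat-relationship ranking
    loss and a drug-effectiveness-comparison ranking loss. Includes warm and
    new-disease evaluation splits, MRR and Hit@K ranking metrics, silhouette
    diagnostics for embedding separation, a synthetic-study generator with
    planted latent structure, and a command-line pipeline driver with
    ablation modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
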