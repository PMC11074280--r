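Package: batchae
Title: Batch-Effect Removal Autoencoders for Multi-Batch LC-MS Expression Matrices
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Autoencoder-based batch-effect correction for liquid
    chromatography mass spectrometry (LC-MS) proteomics and metabolomics
    intensity matrices. Implements a zoo of ten model families combining
    plain and variational autoencoders with five batch-effect removal
    strategies (none, decoder batch mapping with an adversarial
    discriminator, domain-adversarial training through a gradient reversal
    layer, and inverse or reversed batch triplet losses), together with
    batch-mixing metrics (normalized batch entropy, adjusted Rand index,
    adjusted mutual information), pooled-QC reproducibility metrics,
    batch-disjoint repeated-holdout evaluation, class-imbalance-aware
    training with early stopping, sequential hyperparameter search, and a
    synthetic multi-batch data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
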