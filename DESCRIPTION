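Package: dtifuse
Title: Drug-Target Interaction Prediction by Multimodal Fusion of Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-target interactions from multiple precomputed
    drug-drug and target-target similarity matrices. Each similarity network
    is converted into a topological similarity matrix by random walk with
    restart followed by positive pointwise mutual information; the resulting
    matrices are fused into low-dimensional drug and target features by a
    multimodal deep autoencoder; and a deep neural network classifies
    drug-target pairs. Includes SMOTE oversampling for the rare positive
    class, pair-, drug- and target-blinded cross-validation with AUC/AUPR,
    a bootstrap paired t-test, a transfer-learning strategy for small
    datasets, ranking of unknown interactions, and a seeded synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
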