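Package: hyperpcm
Title: Hypernetwork-Predicted QSAR Models for Drug-Target Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("PCM", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Proteo-chemometric (PCM) modeling in which a hypernetwork
    predicts the full parameter vector of a small per-target QSAR network
    from a protein target embedding. Includes a modern-Hopfield-network
    context module that enriches target embeddings against the memory of
    training targets, principled weight initialization (PWI) of the
    hypernetwork heads so predicted QSAR parameters preserve signal
    variance, episodic meta-batch training with oversampling and plateau
    learning-rate decay, chemogenomic data-splitting strategies with
    leakage audits (random, temporal, leave-cluster-compound-out,
    leave-protein-out, cold splits), a metric stack (MCC, AUC, concordance
    index, ROC enrichment, MSE/MAE), a task-conditioned synthetic data
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
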