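Package: tissueshap
Title: Explainable Deep Tissue Classification from RNA-Seq with Shapley
    Attributions
Version: 0.1.0
Authors@R:
    person("Rowan", "Ellis", email = "rowan.ellis@example.org",
           role = c("aut", "cre"))
Description: Trains a convolutional neural network to classify tissue of
    origin from square-image encodings of normalized bulk RNA-seq
    expression, explains the trained model with expected-gradients
    (Shapley-style) feature attributions, and verifies the genes the
    model relies on against a one-vs-rest negative-binomial exact-test
    differential expression analysis and a cluster-separability
    resampling null (UMAP + k-means + V-measure). Includes a
    negative-binomial cohort simulator with planted class-signature
    genes so the whole pipeline is testable without external downloads,
    plus TMM normalization, TPM computation, expression filtering and
    SMOTE class balancing implemented from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    uwot
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
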