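Package: sigmin
Title: Minimal Transcriptional Signatures for Compound Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design, optimise and evaluate minimal transcriptional
    gene signatures for compound target prediction by guilt-by-association.
    Implements batch mean-centring of treatment-instance expression matrices,
    potency-filtered compound-target annotation tables, Pearson-correlation
    nearest-neighbour target prediction with self-match exclusion and a
    set-intersection accuracy metric, signature construction from expression
    statistics (mean, variance, Shannon entropy of binned expression) and
    from interaction-network topology (betweenness, closeness, degree
    centralities, regulator-distance scores), genetic-algorithm optimisation
    of fixed-size signatures, hypergeometric pathway over-representation
    against GMT collections, and a synthetic data generator that plants
    target-driven transcriptional signal for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    withr,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
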