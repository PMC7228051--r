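Package: lbdrank
Title: Neural and Co-Occurrence Approaches to Literature-Based Discovery
Version: 0.1.0
Authors@R:
    person("LBD", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Open and closed literature-based discovery (LBD) on temporal
    biomedical co-occurrence graphs under the ABC paradigm. Provides the
    classical co-occurrence association metrics (count, document count,
    Jaccard, symmetric conditional probability, normalised pointwise mutual
    information, chi-squared, t-test, log-likelihood ratio) with path
    aggregation and accumulation, LINE-style first- and second-order node
    embeddings trained on Jaccard-weighted edges, multilayer-perceptron link
    and path scorers, and a convolutional scorer over stacked path windows.
    Includes tie-median rank evaluation (mean/median rank, MRR, MAP,
    R-precision), case-replication and time-sliced evaluation protocols, a
    synthetic temporal-graph generator with planted triadic closure, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
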