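Package: uff
Title: Unsupervised Feature Filtering by SVD-Entropy
Version: 0.1.0
Authors@R:
    person("UFF", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Unsupervised ranking of features in expression-like matrices by
    their leave-one-out contribution to the SVD-entropy of the data
    (Unsupervised Feature Filtering, UFF), including a fast approximation
    based on first-order rank-one perturbation of the Gram-matrix
    eigenvalues, entropy-based applicability diagnostics (SE/VE), an
    entropy-based instance outlier detector (UDO) with a kth-nearest-
    neighbour baseline, baseline feature selectors, a k-means/Jaccard
    evaluation harness, a seeded synthetic-data generator with planted
    ground truth, and a command-line interface for tab-delimited matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
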