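Package: ktsp
Title: Rank-Based K Top-Scoring Pair Prognostic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Develops and validates K top-scoring pair (K-TSP) prognostic
    classifiers from gene expression data. Scores every gene pair by how
    consistently its within-sample expression ordering switches between two
    prognostic classes, greedily selects K gene-disjoint pairs, and chooses
    the number of pairs and the vote threshold by resubstitution ROC analysis
    under a 100% training-sensitivity constraint. Includes confusion metrics,
    ROC/AUC with bootstrap confidence intervals, Kaplan-Meier and log-rank
    survival comparison, a synthetic cohort generator with planted
    class-switching pairs, tab-delimited/CSV/JSON input-output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
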