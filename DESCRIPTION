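Package: hubdiff
Title: Differential Activity and Organization of Hub Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Supervised differential analysis of hub-centric genetic networks
    between two classes of expression profiles. Scores each hub network for
    differential activity (permutation-calibrated network activity scores
    with empirical false-discovery rates), for differential organization
    (change in hub-interactor Pearson correlation between classes), and for
    enrichment of cellular processes (hypergeometric test on GO-Slim style
    annotations). Includes a synthetic two-class cohort generator with
    planted activity and rewiring effects so the whole pipeline can be
    exercised and validated without access to the original tumor data, plus
    readers and writers for expression, interaction-network (SIF and
    adjacency) and annotation files, K-nearest-neighbour imputation, and
    export of results for standard graph-visualization tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
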