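Package: parenclitic
Title: Parenclitic Network Analysis of Gene Methylation Profiles
Version: 1.0.0
Authors@R:
    person(given = "Package", family = "Author",
           email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject ('parenclitic') networks from gene-level DNA
    methylation profiles. Nodes are genes; edge weights quantify how far one
    subject's pair of methylation levels deviates from a reference model
    fitted on a control group, using either a linear-regression residual
    kernel or a (squared) Mahalanobis-distance kernel. Each network is
    summarized by twelve weighted-graph topology indices (edge-weight,
    degree and shortest-path statistics, diameter, Freeman-style degree
    centralization, efficiency, betweenness centrality), which feed a
    two-step cross-validated random-forest or support-vector-machine
    classifier of disease status. Also provides complementary cumulative
    degree-distribution summaries with power-law fits, a probe-level
    preprocessing stage (coverage filtering, k-nearest-neighbour imputation,
    gene-level averaging), a seeded synthetic-cohort generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
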