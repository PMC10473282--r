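Package: netreconfig
Title: Static and Dynamic Functional Connectome Reconfiguration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how whole-brain functional networks reconfigure
    across cognitive states. Builds static and sliding-window dynamic
    functional connectivity (Pearson correlation, Fisher z) from node time
    series, thresholds networks with a minimum-spanning-tree-backed density
    criterion, computes global graph topology (small-worldness, efficiency,
    clustering, betweenness, Louvain modularity), the modular segregation
    index and its dynamic trajectory, multilayer temporal community detection
    with allegiance matrices and consensus clustering, EZ-diffusion
    decomposition of two-choice behavior, and the repeated-measures
    statistics that relate network reconfiguration to cognitive process.
    Includes a fully specified synthetic-cohort generator with planted state
    effects so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
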