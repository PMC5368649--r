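Package: citm
Title: Collective Influence Maximization in Threshold-Model Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying maximally influential seed sets in the
    Linear Threshold Model (LTM) of cascading processes on networks, where
    cascades exhibit abrupt first-order transitions. Implements exact LTM
    dynamics with incremental giant-active-component tracking, nonlinear
    message passing on directed links with its linearized non-backtracking
    operator, subcritical-path counting and the adaptive CI-TM greedy seed
    selector (including the modified variant that discounts vulnerable
    vertices), alongside classical centrality baselines (degree, adaptive
    degree, k-shell, PageRank, betweenness, closeness, exact greedy).
    Includes synthetic graph generators (Erdos-Renyi, power-law
    configuration model), plain-text edge-list I/O, and experiment
    drivers for critical-seed-fraction tables, subcritical-path timelines
    and activation-time distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
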