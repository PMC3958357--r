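Package: gimmeclust
Title: Data-Driven Subgrouping of Individuals from Directed Functional
    Connectivity Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Organizes heterogeneous samples into data-driven subgroups
    based on directed resting-state functional connectivity. Individual
    lagged and contemporaneous connectivity maps are estimated with a
    unified structural equation model (structural VAR) via a
    group-then-individual iterative search (GIMME). Individuals are then
    clustered by Newman modularity community detection on a correlation
    similarity network of their connection weights, with a fully
    data-driven binarization threshold chosen from modularity stability
    and reachability. Includes degree-preserving perturbation and
    variation-of-information robustness checks, subgroup path-weight
    comparisons with false discovery rate control, a Monte Carlo
    generator of subgroup-structured time series, and motion-scrubbing
    utilities for region-of-interest time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
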