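Package: edame
Title: Inference of Signed Microbial Interaction Networks from Boolean
    Attractors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed, undirected interaction networks from binary
    presence/absence patterns interpreted as attractors of a synchronous
    Boolean threshold ("majority vote") dynamic. Provides exhaustive
    attractor enumeration for small signed networks, node-level attractor
    difference scores that localize edge changes (the sorted-nodes array),
    entropy-shift (ESABO) edge scoring to build an initial network guess,
    and the EDAME refinement loop that iteratively corrects edges until
    the network reproduces a target attractor set. Includes simulation
    benchmarks against mutual information, Pearson and phi-coefficient
    baselines, and utilities for binarizing and aggregating microbial
    relative-abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
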