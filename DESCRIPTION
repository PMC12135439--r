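Package: activegrn
Title: Active Learning for Bayesian Gene Regulatory Network Structure
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for Bayesian active learning of gene regulatory network
    structure from expression data.  Sampled posterior graphs are condensed
    into per-pair edge-state distributions (three DAG states, or four
    essential-graph states including the undirected state), which feed
    acquisition functions -- Edge Entropy, BALD, and their equivalence-class
    variants ECES and EBALD -- that rank candidate single-gene knockout
    experiments.  The package ships reference posterior samplers (exact
    enumeration for small networks and structure MCMC with an interventional
    Gaussian score), a linear-Gaussian knockout simulator emulating the
    DREAM4 GeneNetWeaver data shapes, essential-graph machinery (v-structure
    orientation plus Meek rules), structural-Hamming-distance evaluation, and
    an orchestrated simulate-train-acquire-intervene loop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
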