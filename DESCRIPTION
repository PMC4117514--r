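Package: multriplet
Title: Multi-Labeled Phylogenetic Trees from Rooted Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and comparing rooted binary multi-labeled
    phylogenetic trees (MUL trees), in which several leaves may carry the
    same taxon label, from sets of rooted triplets.  Implements the MTRT
    heuristic for the smallest-MUL-tree problem (an Aho-style top-down
    recursion driven by minimal vertex separators of the triplet auxiliary
    graph), an exhaustive exact solver usable as an optimality oracle on
    small label sets, set- and multiset-based rooted triplet distances for
    MUL trees, a multispecies-coalescent simulator of MUL trees, and an
    experiment harness for consistency-principle studies on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
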