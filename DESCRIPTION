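Package: topoess
Title: Effective Sample Size of Phylogenetic Tree Topologies from MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Convergence diagnostics for posterior samples of phylogenetic
    tree topologies from Bayesian MCMC. Provides topology traces and jump
    distance plots for visual assessment of mixing and autocorrelation, and
    two estimators of the effective sample size (ESS) of sampled topologies:
    the pseudo-ESS (the ESS of distances to randomly chosen focal trees,
    summarised over replicates) and the approximate-ESS (obtained by equating
    expected squared pairwise topological distances of the chain to those of
    a hypothetical independent sample). Topological distances are the
    Robinson-Foulds distance and the path difference, computed on unrooted
    topologies ignoring branch lengths. Includes simulators of unimodal
    SPR-walk chains and bimodal two-set switching chains for validating the
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    coda,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
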