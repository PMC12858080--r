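Package: tadwalk
Title: Target-Search Kinetics on Chromatin Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models protein target search on chromatin-like polymer domains
    represented as networks in contact space. Provides stochastic
    first-passage simulations with one-dimensional sliding, intersegmental
    hops and bulk unbinding/rebinding; exact mean first-passage time theory
    for static (quenched) and dynamically rewired (annealed) networks,
    together with the printed low- and high-connectivity asymptotics;
    freely rotating chain and bead-spring (Lennard-Jones and soft-core)
    polymer conformation generators with conversion to contact networks;
    and Hi-C based analysis of topologically associating domains (TADs),
    including power-law fits of intra-domain contact probability and
    search-time scaling exponents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
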