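Package: clustersync
Title: Cluster Synchronization in Directed Multilayer Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing cluster synchronization in directed,
    weighted, delayed, multilayer networks of coupled dynamical systems.
    Finds balanced (equitable) partitions and their lattice, computes
    breaking vectors and intertwining indices, constructs the irreducible
    coordinate transformation that block-decomposes the transverse
    variational equations, classifies cluster interdependencies
    (independent, intertwined, one-way dependent), and evaluates cluster
    stability through transverse maximum Lyapunov exponents of the
    delay-coupled variational equations, integrated with a fixed-step
    Runge-Kutta scheme and Benettin renormalization.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
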