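Package: arborfield
Title: Mean-Field Theory and Stochastic Simulation of Dendritic Arbor Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling the growth of dense planar dendritic arbors,
    such as those of Drosophila class IV sensory neurons, from the stochastic
    dynamics of their branch tips. Implements a three-state (growing,
    shrinking, paused) mean-field model of branch densities: tip-level drift
    and Green-Kubo diffusion from the transition-rate matrix, analytic
    homogeneous steady states (mean branch length, number and length
    densities, exponential length distributions), marginal-stability
    traveling-wave fronts and the growth/no-growth phase diagram, a
    directed-rod Monte-Carlo simulator with collision-based retraction, a
    moment-reduced numerical solver on a polar grid, Monte-Carlo mesh-size
    (space-filling) statistics for planar segment networks, and morphometry
    for skeletonized arbors (branch classification, radial angles, widths,
    densities, front profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
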