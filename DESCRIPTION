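Package: fgba
Title: Stochastic Cellular Automaton of Tropical Forest-Grassland-Fire Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact continuous-time (Gillespie) simulation of the FGBA
    (forest-grass-burning-ash) probabilistic cellular automaton of tropical
    vegetation and fire on a periodic square lattice, together with the
    analysis toolkit built around it: perimeter and grass-cluster geometry,
    the macroscopic balance equation of forest area change, single-fire loss
    approximations, landscape resilience indicators, noninvasive feedback
    control for tracing unstable equilibria of the bifurcation diagram, and
    mean-field approximations with closed-form steady states and the
    bistability onset ignition rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    mgcv,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
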