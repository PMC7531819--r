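Package: wmflux
Title: Non-Equilibrium Landscape and Flux Analysis of Working-Memory
    Attractor Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the global, non-equilibrium analysis of a reduced
    two-population working-memory circuit. Starting from the stochastic
    dynamics of the NMDA synaptic gating variables, the package solves the
    stationary Fokker-Planck equation on a two-dimensional grid to obtain
    the potential landscape U = -ln(Pss) and the steady-state probability
    flux, locates and classifies attractors (resting, memory and
    intermediate states), measures barrier heights by minimax paths on the
    landscape, solves the backward boundary-value problem for mean first
    passage times, and quantifies the energy cost of persistent activity
    through the entropy production rate. Seeded Euler-Maruyama simulation
    of single trials provides Monte-Carlo cross-checks and transition-path
    densities, and sweep drivers reproduce the stability-flexibility-energy
    tradeoff across recurrent-excitation and mutual-inhibition strengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
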