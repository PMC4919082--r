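Package: rkselect
Title: Stochastic Control and Structured Population Models for r/K Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the evolution of life histories under
    density dependence and internal (diffusion-driven) stochasticity.
    Individual life histories are modelled as controlled stochastic
    differential equations with state-dependent fertility and mortality;
    population dynamics follow a nonlinear structured (age-by-state)
    model whose steady states are characterised by a single fitness
    function.  The package computes this characteristic function by
    Monte Carlo path simulation, by a Feynman-Kac boundary-value solve
    and in closed form for geometric-Brownian-motion life histories;
    solves the Euler-Lotka equation for the intrinsic rate of natural
    increase; finds the density-effect equilibrium and carrying
    capacity; solves the stationary Hamilton-Jacobi-Bellman equation
    for adaptive (evolutionarily stable) strategies including the
    two-resource utilisation model; and integrates the nonlinear
    population dynamics with an individual-based cross-check.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
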