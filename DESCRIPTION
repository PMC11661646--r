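Package: altcushions
Title: Stability of Morphogen-Free Gene Expression Stripe Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spatial-stochastic simulation and stability analysis of a four-gene
    "alternating cushions" stripe pattern, in which nearest-neighbour expression
    domains repress each other weakly and next-nearest-neighbour domains repress
    each other strongly. Provides an exact Gillespie simulator on a cylindrical
    lattice of nuclei with diffusive hopping (next-subvolume method), a
    non-stationary forward-flux sampler for rare pattern-breakdown events,
    phase-space analysis of pattern asymmetry coordinates (survival curves,
    destruction rates, drift and diffusion fields, pseudopotential landscapes),
    perturbation experiments with domain centre-of-mass tracking, and a
    deterministic free-boundary stability theory for expression-domain contact
    zones that predicts the optimal weak-to-strong repression ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve
Config/testthat/edition: 3
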