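Package: tprf
Title: Time-Dependent Random-Effects Poisson Random Field Inference of Selection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian inference of the distribution of selective
    effects of nonsynonymous mutations and of species divergence time from
    per-locus polymorphism/divergence count tables (generalized 2x3
    McDonald-Kreitman tables) of two closely related species. Implements a
    time-dependent Poisson random field model whose six category means are
    functionals of the Wright-Fisher diffusion transition density (solved by
    Crank-Nicolson), an adaptive-directional adaptive-Metropolis (ADAM) MCMC
    sampler with Gibbs updates for mutation rates, a model-faithful synthetic
    data generator, posterior summaries including positively-selected
    population proportions, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
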