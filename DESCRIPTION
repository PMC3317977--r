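Package: tdprf
Title: Time-Dependent Poisson Random Field Inference of Selection and
    Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a time-dependent Poisson random field model to
    polymorphism and divergence data from two recently diverged species.
    Per-locus DOHRS tables (fixed differences, sites polymorphic in one
    sample, and sites polymorphic in both samples, separately for silent
    and replacement sites) are modelled as independent Poisson counts
    whose means follow from a Wright-Fisher diffusion without assuming
    post-divergence equilibrium.  The backward Kolmogorov equation is
    solved by a Crank-Nicolson scheme, frequency-spectrum integrals use
    Gauss-Legendre quadrature with a logarithmic substitution at the
    singular endpoint, and per-locus selection coefficients, mutation
    rates, and the species divergence time are estimated by hierarchical
    Bayesian Markov chain Monte Carlo.  Includes a simulator for
    parameter-recovery studies and a small command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
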