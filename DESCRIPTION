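Package: divechaos
Title: Chaos-Theoretic State-Space Analysis of Marine-Mammal Dive Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs a behavioral state space from a one-dimensional
    depth record by time-delay embedding, selects the embedding delay and
    dimension from the data (first minimum of auto-mutual information,
    false-nearest-neighbor knee), computes sliding-window attractor
    invariants (Euclidean distance from the origin, phase-space kinetic
    energy, maximum Lyapunov exponent by the Rosenstein method,
    Grassberger-Procaccia correlation dimension, dominant wavelet period),
    decodes behavioral states by Gaussian-mixture clustering of those
    invariants with AIC model selection, and summarizes diurnal patterns
    and time budgets. Includes a semi-Markov dive-record simulator with
    known ground-truth states so that every stage of the pipeline can be
    validated against construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
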