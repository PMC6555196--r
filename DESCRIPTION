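Package: ephapsis
Title: Closed-Loop Ephaptic Coupling in Compartmental Spiking Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compartmental models of spiking neurons (spherical somata,
    cylindrical neurites), computes the extracellular potentials generated by
    their transmembrane currents with line- and point-source approximations,
    and feeds those potentials back into the membrane dynamics as an ephaptic
    current that is solved self-consistently at every time step. Includes an
    open-loop (post-hoc local field potential) mode, Hodgkin-Huxley and passive
    membrane models, stimuli, chemical and electrical synapses, SWC morphology
    import, an independent fixed-step implicit reference integrator, and
    spike-train cross-correlation tools for quantifying ephaptic phase locking
    in axon bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
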