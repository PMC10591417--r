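Package: senesim
Title: Spatially Explicit Individual-Based Simulation of the Evolution of
    Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, individual-based simulator of the evolution of
    aging in a viscous population.  Haploid agents with binary genomes
    (fecundity loci matched against a moving or static environmental
    optimum, plus senescence loci that set a linear age-dependent
    mortality term) live on a toroidal lattice updated by asynchronous
    birth/death Monte Carlo steps.  Includes the observables, parameter
    sweeps, invasibility protocols and model variants needed to study
    when directional selection coupled with kin selection favours an
    evolved, heritable rate of aging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
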