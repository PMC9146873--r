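Package: spinalcpg
Title: Bilateral Spinal Locomotor Central Pattern Generator Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of the bilateral mammalian spinal
    locomotor network: Hodgkin-Huxley neuron populations with persistent
    sodium (INaP) dependent bursting, flexor and extensor half-centers,
    commissural (V0D, V0V, V3, CINe) and ipsilateral inhibitory (V1, V1-1,
    V2b, Ini) interneuron populations wired by a probabilistic connectome.
    Supports drug-induced (leak-reversal depolarization) and brainstem-drive
    rhythm induction, midsagittal hemisection, and optogenetic manipulation
    of V1 neurons via archaerhodopsin and channelrhodopsin conductances.
    Includes an analysis layer that converts spike rasters into population
    rate histograms, burst trains, oscillation frequencies, and phase or
    coordination metrics, plus named experiment protocols and parameter
    sweeps with tidy outputs and ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
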