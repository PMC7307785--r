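Package: cldyn
Title: Chloride Dynamics and Synaptic Inhibition in Multi-Compartment
    Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based multi-compartment neuron simulation with
    dynamic intracellular chloride: KCC2 cotransport, GABA-A receptor
    chloride/bicarbonate flux, longitudinal diffusion, and continuously
    recomputed reversal potentials.  Includes a calibration pipeline that
    estimates the KCC2 pump strength from chloride-recovery recordings,
    synthetic-data generators for perforated-patch style experiments,
    and analysis tools for input-output curves, half-max offsets, the
    chloride index, and instantaneous firing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
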