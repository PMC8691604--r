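Package: ctdcs
Title: Cellular Effects of Cerebellar Transcranial Direct Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale modelling pipeline for the cellular response of
    cerebellar neurons to weak uniform electric fields such as those induced
    by transcranial direct current stimulation (tDCS). Provides a deterministic
    multicompartment cable simulator with quasi-uniform extracellular field
    coupling and selective membrane-bias manipulations, reduced Purkinje and
    deep-cerebellar-nucleus models plus a 65-compartment granule cell model,
    generators for the synaptic drives used in the experiments, spike-train
    pattern metrics (burst decomposition, silence periods, phase-response
    curves, relay fidelity), synthetic folded-cortex geometry with voxelised
    electric-field grids, and projection of per-cell sensitivity curves onto
    cortical iso-surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    RNifti,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml
Config/testthat/edition: 3
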