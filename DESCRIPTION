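Package: micniche
Title: Multi-Scale Agent-Based Simulation of Myeloma-Initiating-Cell Niches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A hybrid discrete-continuum, three-dimensional agent-based model
    of multiple myeloma growth in a bone-marrow lattice, centred on the
    positive feedback loop between myeloma-initiating cells (MICs) and bone
    marrow stromal cells: MICs secrete SDF-1, stroma stiffens in response, and
    stiffer niches boost MIC proliferation, self-renewal and drug resistance.
    Includes the full myeloma lineage (MIC, progenitor, mature and terminal
    cells with passage limits), an explicit finite-difference SDF-1
    reaction-diffusion solver, Bortezomib and AMD3100 treatment with a
    clinical dosing schedule, factorial dose-sweep orchestration, and Loewe
    additivity synergy analysis (effect surfaces, Gaussian smoothing, E50/E100
    isoboles, combination indices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
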