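Package: redoxtf
Title: Single-Cell Dynamics of Redox-Regulated Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-cell time-lapse dynamics of
    hydrogen-peroxide-responsive transcription factors. A mechanistic
    two-threshold model of peroxiredoxin hyperoxidation and sulfiredoxin
    repair generates synthetic cell populations (bolus or continuous H2O2
    exposure, genetic and chemical perturbations, heterogeneous kinetics,
    dose-dependent cell death). The analysis pipeline detects FOXO1
    nuclear entry/exit episodes and p53 accumulation onsets, builds
    event-aligned ensembles with median/MAD summaries, computes windowed
    autocorrelation of p53 trajectories with fate-stratified comparison,
    and classifies fixed-timepoint snapshots into activation quadrants
    with dose-response summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
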