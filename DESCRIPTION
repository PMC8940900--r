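Package: circuitphys
Title: Behavioral, Fiber-Photometry and Patch-Clamp Analysis for Stress-Circuit Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis chain for chronic-social-defeat-stress circuit
    studies: behavioral scoring from video-tracking trajectories (social
    interaction ratio, elevated plus maze, open field, sucrose and female-urine
    preference) with susceptible/resilient phenotype classification;
    fiber-photometry processing (isosbestic control fit, dF/F, session
    z-scoring, compartment AUC, MAD-threshold calcium-event detection,
    peri-event dynamics); patch-clamp feature extraction (cell-attached firing,
    excitability, rheobase, Ih current, sag); and a normality-gated
    correlation/group-comparison stage. Includes seeded synthetic-data
    generators (arena-confined trajectories, two-channel photometry with
    bleaching and motion artifacts, a spiking membrane model with an Ih
    conductance) that retain ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    pracma,
    car,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
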