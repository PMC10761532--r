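Package: aavterm
Title: Quantifying AAV Genome-Packaging Termination at Inverted Terminal Repeats
Version: 0.1.0
Authors@R:
    person("Vector", "Analytics", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Tools for characterizing heterogeneous recombinant
    adeno-associated virus (rAAV) packaging when the vector genome is much
    shorter than the capsid capacity. Enumerates the packageable multimer
    genome species predicted by a replication-intermediate model, predicts
    particle masses (capsid plus counterion-corrected ssDNA), simulates and
    quantifies charge-detection mass-spectrometry (CD-MS) single-ion data and
    alkaline-gel densitometry lanes, and converts packaged-species abundances
    into per-ITR termination probabilities with cross-method comparison. A
    JSON-configured pipeline and command-line interface tie the stages into
    reproducible end-to-end runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
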