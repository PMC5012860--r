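Package: histoneub
Title: Histone PTM Proteomics Post-Processing and Ubiquitylation Quantification
Version: 1.0.0
Authors@R: person("Maintainer", "Histoneub", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for bottom-up histone post-translational-modification
    proteomics with propionylation derivatization: elemental-formula mass
    arithmetic and propionylation-adjusted variable modification masses,
    in silico Arg-C/trypsin digestion, Percolator-style PSM table handling
    with deltaCn re-scoring and FDR filtering, a greedy retention-time
    consistency filter for modified histone peptides under a modification
    elution partial order, extracted-ion-chromatogram area quantification
    with free-ubiquitin normalization, fluorescence-polarization one-site
    Kd fitting, linear rate fits, size-exclusion calibration, Gaussian
    volume-histogram fits, and a thresholded two-channel 5mC image
    statistic. Includes seeded synthetic-data generators with ground truth
    for end-to-end testing, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
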