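Package: chromakin
Title: Single-Molecule Chromatin Binding Kinetics and Cohesin Loop Extrusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-molecule tracking experiments on chromatin-binding
    proteins (cohesin, CTCF) in live embryos, and rule-based simulation of
    cohesin-mediated loop extrusion. Covers illumination-scheme bookkeeping and
    nearest-neighbour track linking, Brownian-mixture fitting of jump-distance
    distributions with AIC model selection, interlaced time-lapse (ITM/TACO)
    binding-class analysis, inversion of multi-condition fluorescence survival
    distributions into dissociation-rate spectra, an equilibrium two-class
    target-search model, center-border-distance radial analysis of nuclear
    binding positions, a 1D lattice loop-extrusion engine with impermeable CTCF
    sites, and contact-map statistics (P(s), slopes, observed/expected pile-ups).
    A seeded synthetic-data generator provides ground-truth-labelled input for
    every stage so that all analyses are testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
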