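Package: hdxbind
Title: Differential Hydrogen/Deuterium Exchange Analysis and One-Site
    Binding Thermodynamics for Membrane Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Peptide-level analysis of differential hydrogen/deuterium
    exchange mass spectrometry (HDX-MS) experiments comparing two protein
    states: deuterium-uptake summaries, hybrid significance testing
    (global threshold from the pooled replicate standard deviation
    combined with Welch's t-test), consensus mapping of peptide-level
    significance onto residues via overlapping peptides, classification
    of peptides into dynamic groups, and per-residue annotation of
    structure models. Includes an EX2 forward-simulation module that
    generates ground-truth two-state systems, nonspecific-digestion
    peptide maps, and replicate uptake tables for validation, and a
    one-site independent-binding model for isothermal titration
    calorimetry (ITC): thermogram simulation, heat-of-dilution
    subtraction, nonlinear least-squares fitting of Ka and enthalpy with
    fixed stoichiometry, and signed fold-of-affinity comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
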