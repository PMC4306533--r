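Package: capaffinity
Title: Cap-Analogue Binding Affinity and Thermodynamics for eIF4E-Family Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mRNA 5' cap analogue binding to
    eIF4E-family translation initiation factors from fluorescence
    quenching titrations. Implements the single-site ligand-depletion
    binding isotherm with a free-ligand emission term, raw-intensity
    corrections (dilution, inner filter effect), nonlinear least-squares
    estimation of association constants with inverse-variance pooling of
    replicates, conversion to standard Gibbs free energies and
    ligand-transition energy tables with first-order error propagation,
    cap-analogue chemistry (name parsing, Henderson-Hasselbalch net
    charge), comparative-alignment detection of paralog-family
    discriminating residues, and a synthetic titration generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    MASS,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
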