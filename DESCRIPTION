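Package: hdxkin
Title: Prediction of Hydrogen-Deuterium Exchange Kinetics from Structural Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative prediction of hydrogen-deuterium exchange (HDX-MS)
    kinetics of protein fragments from structures and conformational
    ensembles. Computes per-residue phenomenological protection factors from
    heavy-atom contacts and amide hydrogen bonds, sequence- pH- and
    temperature-dependent intrinsic amide exchange rates, residue- and
    fragment-level deuterium uptake curves with crystal-only, ensemble-mean
    and per-frame averaging modes, comparison against experimental uptake
    tables, validation of peptide fragment assignments by monoisotopic mass,
    and structural descriptors (solvent-accessible surface area, buried
    interface area, root mean-square fluctuations). Includes a deterministic
    synthetic-structure generator for testing and method exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
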