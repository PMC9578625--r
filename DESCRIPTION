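Package: shiftlda
Title: Amino-Acid Residue Type Recognition from NMR Chemical Shifts by
    Linear Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "shiftlda", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recognizes amino-acid residue types from the backbone and
    beta chemical shifts of spin systems observed in NMR spectra of
    intrinsically disordered proteins.  A linear discriminant analysis
    classifier with pooled class covariance is trained on assigned
    chemical-shift lists (BMRB NMR-STAR entries or plain tables), with
    joint Pareto scaling of training and query shifts and automatic
    restricted models for spin systems with missing shifts.  Includes
    protein-level leave-one-out cross-validation, permutation feature
    importance, row-normalized confusion charts, mapping of spin-system
    chains onto a protein sequence with amino-acid-sequence filtering,
    assignment transfer between 2D peak lists, a synthetic spin-system
    generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
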