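Package: pnatherm
Title: Nearest-Neighbor Thermodynamics for Peptide Nucleic Acid Homoduplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the binding thermodynamics of peptide
    nucleic acid (PNA) homoduplexes. Decomposes duplex binding enthalpies
    into nearest-neighbor stack, helix-initiation and terminal-GC terms by
    error-weighted linear least squares, and predicts duplex enthalpies
    from sequence. Includes two-state van't Hoff analysis of UV melting
    curves, post-processing of end-point (MM-GBSA) binding-energy tables
    with standard-state and linear-calibration corrections, Watson-Crick
    hydrogen-bond melting-event statistics, and synthetic-data generators
    that emulate every input so the full pipeline is testable without
    simulation trajectories or raw absorbance data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
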