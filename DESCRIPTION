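Package: abscan
Title: Epitope Scanning and CDR-RMSD Analysis for Antibody Humanization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-guided humanization of rodent monoclonal
    antibodies. Delimits framework and complementarity-determining regions
    (CDRs) of variable-domain sequences under the Kabat, Chothia and IMGT
    conventions; scans framework regions against a set of human template
    sequences for linear (sliding 6-mer) and conformational (<5 Angstrom
    residue-pair) epitopes; proposes human substitutions and builds
    humanized and refined (back-mutated) sequence variants; superposes CDRs
    by the Kabsch algorithm and identifies conformation-critical framework
    residues from per-mutant CDR RMSD values at a 1.5 Angstrom threshold;
    and analyses RMSD-versus-time series from molecular-dynamics
    trajectories for convergence. Includes deterministic synthetic-fixture
    generators so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
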