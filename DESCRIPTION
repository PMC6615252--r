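Package: cspkit
Title: NMR Chemical Shift Perturbation Titration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of protein-ligand titrations followed by NMR chemical
    shift perturbation (CSP). Computes the weighted amide 1H/15N CSP statistic
    per residue, fits per-residue dissociation constants under a 1:1
    fast-exchange binding model with exact ligand depletion, aggregates them
    into an averaged K_D with a spread-based error, compares matched
    conditions (differential CSP) to locate allosteric or interface patches,
    emits CNS-style ambiguous interaction restraints for data-driven docking,
    maps per-residue values onto PDB B-factors, and includes a synthetic
    titration generator for end-to-end validation. Peptide mass bookkeeping
    utilities are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
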