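Package: emmsol
Title: Absolute Chemical Potentials and Solubility via the Einstein Molecule Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing absolute chemical potentials of molecular
    solids and of solutes in solution with alchemical free energy
    calculations, and for locating the solubility point where the two
    chemical potentials cross. Implements the Einstein molecule reference
    state (a harmonically tethered ideal solid with one fixed atom), toy
    crystal and solution energy models with periodic boundaries, a Metropolis
    and Langevin sampling engine, the TI, EXP, BAR and MBAR free energy
    estimators with phase-space overlap diagnostics, Widom test-particle
    insertion as an independent oracle for excess chemical potentials, and a
    solubility assembler that interpolates solution chemical potentials
    across concentrations and reports the crossing or an insolubility
    verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
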