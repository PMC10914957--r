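Package: membind
Title: Peptide-Membrane Binding Analysis for Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for characterizing how an amyloid-beta (1-40)
    peptide binds a mixed POPC/POPS/cholesterol bilayer in molecular dynamics
    ensembles. Provides periodic-boundary-aware contact counting, perpendicular
    center-of-mass distances and residue insertion depths, geometric hydrogen
    bond detection, DSSP-style secondary structure assignment, free-energy
    landscapes over collective variables with basin and microstate extraction,
    a four-class binding-model classifier, and replica exchange with solute
    tempering (REST2) ladder construction and exchange diagnostics. A
    synthetic-data module generates toy peptide-bilayer trajectories with
    planted ground truth so every stage of the pipeline can be validated
    without external trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
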