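Package: helixforge
Title: Analytical Parameterization of Protein Helices and Their Motions
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a straight protein helix as four co-axial sub-helices (one
    per backbone atom type N, C-alpha, C, O) sharing an axis, pitch and angular
    turn per residue, and fits the 19 free parameters of that model to observed
    backbone coordinates by Levenberg-Marquardt least squares. From the fitted
    parameters it derives helix diameter, winding (angular turn per residue),
    3/10 - alpha - pi form classification, torsional position, interhelix
    angle and distance, longitudinal sliding, differential winding, and the
    mapping between backbone dihedral angles and helical twist. Includes spiral
    (wenxiang) diagram generation, a synthetic-fixture generator that writes
    standard PDB files with known ground truth, and command-line style drivers
    for fitting, state-to-state comparison and multi-panel parameter surveys
    across families of structures such as the rhodopsin photocycle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils-geometry.R'
    'helix-model.R'
    'spiral.R'
    'interhelix.R'
    'structure-io.R'
    'cli.R'
    'fixtures.R'
    'helixforge-package.R'
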