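Package: oligoring
Title: Ring-Shaped Peptide Oligomer Modelling by Conformational Selection and Screw Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ring-shaped oligomer models of an amyloid peptide from a
    conformational ensemble. Provides ensemble observables (Karplus
    back-calculated three-bond J-couplings, secondary chemical shifts against a
    random-coil reference, secondary-structure propensities, RMSD/Rg free-energy
    surfaces) and gromos conformational clustering to select a protomer
    conformation; coarse-grained rigid-body self-docking with six
    degree-of-freedom minimization, pose clustering and energy ranking to
    propose dimer interfaces; screw-transformation (Chasles) geometry to
    extract helical parameters from a dimer, enumerate and filter ring
    candidates; and Monte-Carlo cyclization with exact N-fold closure plus ring
    metrics, inter-protomer contact maps and ring-on-ring stacking. A synthetic
    structure generator (internal-coordinate backbone building, two-state
    ensembles, ideal screw dimers) supplies every input without molecular
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
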