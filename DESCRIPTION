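Package: poroifem
Title: Poroelastic Immersed Finite Element Framework for Cardiac Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the myocardium as a saturated poroelastic medium (an
    incompressible skeleton perfused by pore blood) immersed in a viscous
    incompressible bathing fluid. Provides the pointwise constitutive laws
    (Biot-modulus pore-pressure law, Mooney-Rivlin-type and Holzapfel-Ogden
    skeleton energies, distributed perfusion sources), a Lagrangian
    finite-element split-step Darcy solver on deforming hexahedral meshes, a
    quasi-static nonlinear solid solver, an immersed-boundary coupling on a
    staggered Cartesian grid with regularized-delta spreading and a
    projection-based fluid step with volumetric sources, mesh generators for
    benchmark cubes and an idealized left ventricle with rule-based fibres,
    and end-to-end drivers for swelling, drainage, fibre-reinforced and
    perfused-ventricle scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
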