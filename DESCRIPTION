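Package: headimpact
Title: Constitutive Models and Reduced-Order Simulation for Rodent Head
    Impact-Acceleration Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale toolkit for the biomechanics of the rodent closed-head
    impact-acceleration (Marmarou-type) injury model. Implements the soft-tissue
    constitutive laws used in finite-element rat head models as pure functions of
    deformation and time: Kelvin-Maxwell shear relaxation, transversely isotropic
    fiber-reinforced hyperelasticity of Weiss type with Prony-series
    quasi-linear viscoelasticity, and a tabulated rate-dependent foam. Provides
    continuum-kinematics utilities with a finite-difference Cauchy-stress oracle,
    a hereditary-integral creep model of dynamic cortical deformation, a planar
    rigid-body drop-impact simulator with helmet-angle and contact-stiffness
    parametric sweeps, peak-kinematics extraction, experimental response
    corridors, and a CORA-like biofidelity rating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
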