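# headimpact

Desk-scale biomechanics toolkit for the rodent closed-head
**impact-acceleration (Marmarou-type) injury model** — the most widely used
laboratory model of traumatic axonal injury, in which a guided free-falling
weight strikes a metal helmet disk glued to the skull of an anesthetized rat
resting on a foam bed. Finite-element rat head models built for this
experiment combine a handful of well-defined ingredients: viscoelastic shear
laws for brain tissue, a transversely isotropic fiber-reinforced
hyperelastic law for aligned white-matter tracts, a rate-dependent foam bed,
and corridor/CORA-style biofidelity ratings against the measured head
kinematics. `headimpact` implements those ingredients as plain, testable R
functions plus two reduced-order simulators, so the constitutive layer and
the parametric trends of such models can be studied, verified and taught
without a commercial FE solver or a proprietary mesh.

Intended users: injury-biomechanics researchers and students who want an
inspectable reference implementation of these material laws and validation
metrics, and modelers who need a fast surrogate for sensitivity studies of
the impact-acceleration experiment.

## The models

**Kelvin–Maxwell shear relaxation** (isotropic brain tissue, meninges,
disc):

    G(t) = G_inf + (G_0 - G_inf) exp(-beta t)

with `G_0`, `G_inf` in kPa and `beta` in 1/ms, e.g. gray cortex
5.16 / 1.54 / 0.05.

**Fiber-reinforced hyperelasticity** (corpus callosum, brainstem tracts):

    W = C1 (I1b - 3) + C2 (I2b - 3) + F(lambda) + K/2 [ln J]^2

with isochoric invariants `I1b`, `I2b`, fiber stretch `lambda = |F a0|`, and
the Weiss-type uncrimping fiber law

    dF/dlambda = 0                                  lambda <= 1
               = C3/lambda [exp(C4 (lambda-1)) - 1] 1 < lambda < lambda*
               = (C5 lambda + C6)/lambda            lambda >= lambda*

where `C6` enforces stress continuity at the uncrimping stretch `lambda*`.
Shear viscosity is a Prony series `g(t) = sum S_i exp(-t/T_i)` acting on the
deviatoric stress (quasi-linear viscoelasticity with an exact recursive
update). `calibrate_fiber_params()` solves for the fiber constants that make
the along-fiber tangent stiffness twice the cross-fiber one at
`lambda = 1.02`, the constraint used for white matter in this model family.

**Reduced-order simulators**: a hereditary-integral creep model of the
dynamic cortical deformation (vacuum suction) experiment, and a planar
rigid-body drop-impact model (impactor z; head x, z, pitch; body z) with a
tilted unilateral penalty contact, a rate-dependent foam bed and a neck
spring-damper, which reproduces the qualitative parametric structure of the
full model: the helmet-angle linear/rotational trade-off and the
contact-stiffness trends.

**Validation metrics**: peak extraction in the experiment's time windows,
mean ± sd corridors, and a documented CORA-like rating in [0, 1] (corridor
containment plus phase/size/shape cross-correlation sub-ratings).

## Worked example

```r
library(headimpact)
lib <- default_material_library()
lib[["gray cortex"]]
#> Kelvin-Maxwell material 'gray cortex': G0 = 5.16 kPa, Ginf = 1.54 kPa, beta = 0.05 /ms
relaxation_modulus(lib[["gray cortex"]], c(0, 10, 1e9))
#> [1] 5.160000 3.735641 1.540000
lib[["corpus callosum"]]
#> Transversely isotropic material 'corpus callosum': C1 = 0.77, C2 = 0, C3 = 0.03401, C5 = 4.622 kPa; C4 = 50; lambda* = 1.02
#>   Prony terms (S, T ms): (0.5, 20) (0.2, 2)

res <- simulate_impact(impact_config())   # 450 g impactor at 6.15 m/s
res
#> Impact result: v0 = 6.15 m/s, helmet angle 0 deg (sagittal)
#> Peaks (contact at 0.082 ms):
#>   linear acc       1938.4 g     at 0.433 ms
#>   omega_y neg      -72.91 rad/s at 0.799 ms
#>   omega_y pos       50.17 rad/s at 3.749 ms
#>   impactor disp    -61.88 mm    at 15.000 ms
#>   pulse duration 0.797 ms; energy residual 0.00298% of input
```

The relaxation call returns the instantaneous modulus (5.16 kPa), the
modulus after 10 ms of relaxation, and the long-term plateau (1.54 kPa).
The impact peaks show the experiment's canonical pattern: the linear
acceleration peak within the first millisecond of contact, a negative
(extension) angular-velocity peak within 2 ms followed by the opposite
(flexion) peak a few milliseconds later, and a negative impactor excursion
into the foam. The reduced model targets these signs, timings and trends —
not the absolute peak magnitudes of any particular full-FE model.

Parametric sweeps tabulate percent changes against the flat-helmet baseline
(`sweep_helmet_angle()`, `sweep_contact_stiffness()`); a backward-tilted
helmet raises linear acceleration while weakening the extension peak, a
forward tilt does the reverse, and the two changes are negatively rank
correlated across cases.

A thin command-line front end is included at `inst/cli/headimpact.R`
(subcommands `material-test`, `simulate`, `sweep`, `rate`, `fixtures`).

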