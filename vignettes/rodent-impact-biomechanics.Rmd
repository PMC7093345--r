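---
title: "Methods: constitutive laws and reduced-order simulation of the rodent impact-acceleration experiment"
author: "headimpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constitutive laws and reduced-order simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headimpact)
```

## Scope and philosophy

`headimpact` implements the material laws, validation metrics and parametric
structure of finite-element models of the rodent impact-acceleration (IA)
head-injury experiment as a desk-scale toolkit. Two things it deliberately is
not: a finite-element solver (materials are evaluated on homogeneous
deformation states only, and the drop impact is a planar rigid-body model),
and a reproduction of any specific full-FE model's absolute outputs. The
package's claims are of three kinds: *parameter anchors* (the constitutive
functions return the tabulated moduli exactly), *oracle equivalence* (the
analytic stress matches an independent finite-difference derivative of the
energy), and *trend fidelity* (the reduced impact model reproduces signs,
orderings and timings of the parametric effects, not magnitudes).

## Constitutive layer

### Kelvin–Maxwell shear relaxation

Isotropic brain tissue, the pia-arachnoid complex and the intervertebral
disc follow `G(t) = Ginf + (G0 - Ginf) exp(-beta t)` with the tabulated
`(G0, Ginf, beta)` per tissue. Units are kPa and 1/ms; `t` is in ms. This
pairing is self-consistent, so the constitutive layer stays in the table's
units while the impact simulator converts to SI — the dominant failure mode
in this domain is silent unit mixing, so every field name carries its unit
suffix. The decay kernel is the standard bounded, non-increasing relaxation
convention: a relaxation function must satisfy `G(0) = G0 >= G(t) -> Ginf`,
which fixes the sign of the exponent.

### Fiber-reinforced hyperelasticity

White-matter tracts with aligned axons (corpus callosum, brainstem tracts)
use a Mooney–Rivlin matrix with a single fiber family:
`W = C1(I1b - 3) + C2(I2b - 3) + F(lambda) + K/2 (ln J)^2`. Choices worth
recording:

* **Branch partition.** The uncrimping law is implemented on
  `lambda <= 1` / `1 < lambda < lambda*` / `lambda >= lambda*` — the only
  self-consistent partition: crimped fibers carry no compressive load, the
  toe region stiffens exponentially, and straightened fibers respond
  linearly.
* **Continuity constants.** `C6 = C3[exp(C4(lambda*-1)) - 1] - C5 lambda*`
  is the unique value making the fiber stress continuous at `lambda*`
  (verified to 1e-9 relative in the tests). The calibration additionally
  sets `C5 = C3 C4 exp(C4(lambda*-1))`, which makes the stress C1-continuous
  there, so tangent-stiffness probes straddling `lambda*` are well defined.
* **Matrix split.** Only the small-strain matrix shear modulus is
  constrained by the source data, so the default split is neo-Hookean
  (`C2 = 0`, `2 C1 = matrix modulus`); both constants remain user-settable.
* **Fiber stretch.** `lambda = |F a0|` without deviatoric projection. Near
  incompressibility (`K = 2 GPa` versus kPa-scale shear moduli) the
  difference is negligible, and the unprojected form is the simpler
  contract.
* **Calibration.** `calibrate_fiber_params()` holds `lambda* = 1.02` and
  `C4 = 50` fixed (toe region spanning the stated 2% stretch; the exact
  toe shape is not identifiable from a single stiffness ratio) and solves
  `C3` by bisection (`uniroot`) so the along-fiber : cross-fiber uniaxial
  tangent-stiffness ratio at `lambda = 1.02` hits the target (2.0 for both
  white-matter entries; the brainstem matrix is twice the corpus-callosum
  matrix). The tangent probe is a central difference of the analytic Cauchy
  stress at `h = 1e-5` on incompressible uniaxial states.
* **Viscoelasticity.** Prony terms act as overstresses on the deviatoric
  Cauchy stress with the recursive exponential update
  `h_{k+1} = e^{-dt/T} h_k + S (T/dt)(1 - e^{-dt/T}) (dev sigma_{k+1} - dev sigma_k)`,
  exact for stress histories linear within a step and unconditionally
  stable. The `S_i, T_i` pairs for the white-matter materials are **documented
  stand-ins** (0.5/20 ms, 0.2/2 ms), chosen to give a relaxed fraction
  comparable to the gray-matter Kelvin–Maxwell rows; the published record
  does not tabulate them.

### Foam

The supporting foam is a tabulated family of compressive stress–strain
curves indexed by strain rate. Interpolation is linear in strain on each
curve and piecewise-linear in `log10(rate)` between neighbouring curves —
the standard treatment for tabulated rate-dependent foams, which preserves
the family's monotonicity. Rates outside the table clamp to the nearest
curve; strains beyond the last breakpoint continue the final segment
linearly and are flagged in the result's `extrapolated` attribute rather
than erroring, because a transient solver may legitimately probe past the
table for a few steps.

## Kinematics and the stress oracle

`cauchy_stress_numeric()` is the package's independent verification path:
`sigma = J^{-1} (dW/dF) F^T` by central differences on the nine components
of `F` with a relative step of 1e-6 (balancing truncation against round-off
for kPa-scale energies with a GPa-scale volumetric penalty), plus one
Richardson refinement if the result is asymmetric beyond 1e-6 relative. It
is used only in tests — the analytic stress never calls it — so agreement on
random admissible deformation gradients (100 draws, `J` in [0.9, 1.1]) is a
genuine two-route check.

## The reduced drop-impact model

A planar rigid-body model with five degrees of freedom: impactor `z`
(guided, vertical only), head `x`, `z`, pitch, and body `z`. Design
decisions, in the order they matter:

* **Contact.** A unilateral linear penalty spring-dashpot between the
  impactor face and the helmet point, force-free whenever the gap is open.
  The default stiffness (600 N/mm) is calibrated so the baseline
  acceleration pulse peaks within 1 ms of contact, the experiment's
  signature timing; "rigid" contact is stiffness × 100. A Hertzian law
  would be equally defensible; the data constrain only the timing, so the
  linear law is the simpler documented choice.
* **Helmet angle mechanism.** The contact normal is tilted by the helmet
  angle (plus the current head pitch), splitting the impulse into a normal
  component and a tangential component with a moment arm about the head
  centre of mass. The helmet point sits posterior of the head COM
  (−2.5 mm), which makes the first rotational phase an extension (the
  negative angular-velocity peak) and — through the work-consistent coupling
  between rotation and contact-point velocity — produces the observed
  trade-off: tilts that deepen the extension peak relieve the contact and
  lower the linear acceleration, and vice versa. Sideways tilts reuse the
  planar model with the in-plane impulse reduced by `cos(angle)` and the
  out-of-plane component carried as a lateral-force bookkeeping channel;
  the model claims trend fidelity only.
* **Neck and body.** The head couples to the body through a rotational
  spring-damper on pitch; the translational neck spring acts through the
  COM so that plunge and pitch stay cleanly separable. Head pitch inertia
  and all neck constants are calibration artifacts (the experiment does not
  measure them), tuned once so the angular velocity shows its first
  (negative) peak within 2 ms of contact and the opposite second peak near
  4–5 ms, then frozen.
* **Foam force.** `F = sigma(eps, eps_rate) A` with strain measured over
  the crushable thickness; unloading follows a scaled path (hysteresis
  factor 0.2) blended smoothly over the rate-reversal so the integrator
  sees a continuous force.
* **Integration.** Fixed-step classical Runge–Kutta (via `deSolve::rk4`) at
  `dt = 0.001 ms` over 15 ms, deterministic, no randomness anywhere in the
  simulator. The contact oscillation is resolved by hundreds of steps even
  in the rigid case, and halving `dt` moves the peak metrics by well under
  1%.
* **Energy audit.** Every force element's absorbed power is recorded during
  integration and re-integrated by independent trapezoidal quadrature;
  kinetic + potential + absorbed must equal the initial total at every
  sample. The baseline run closes to ~0.003% of the impact energy; the test
  threshold is 1%. This is the integrator's primary correctness check — a
  sign error in any force/velocity pairing shows up here immediately.

Reported peak metrics follow the experiment's windows: linear-acceleration
peak within (0, 1] ms of contact, negative angular-velocity peak within
(0, 2] ms, positive peak within (2, 15] ms, impactor displacement signed
negative into the foam. The percent-change tables report `Wy(n)` as the
magnitude of the negative peak, so a deeper extension peak counts as an
increase — the convention under which the sweep table's signs mirror the
experimental report: a backward tilt raises linear acceleration and weakens
the extension peak (positive `Linear Acc`, negative `Wy(n)` entries), a
forward tilt does the reverse, and the two rows are negatively rank
correlated across the angle cases.

## Suction (DCD) creep model

The cortical-suction experiment is reduced to a standard-linear-solid creep
compliance `Jc(t) = Jinf - (Jinf - J0) e^{-t/tau}` driven by the pressure
pulse through a hereditary integral (same exact recursion as the Prony
update). Elastic and elasto-plastic membrane kinds collapse to the
quasi-static compliance — they respond without lag, which is exactly the
qualitative feature that distinguishes the membrane models in the
experiment: only the viscoelastic membrane lags the pressure during loading
and unloading. Compliance values (`J0 = 0.01`, `Jinf = 0.03` mm/kPa,
`tau = 15 ms`) are order-of-magnitude stand-ins giving sub-millimetre
deformations at the experiment's 14–28 kPa suction levels.

## Biofidelity rating

CORA proper is a proprietary multi-parameter standard; the package
implements a documented open analogue on the same [0, 1] scale with 1 a
perfect match: a corridor sub-rating (1 inside mean ± sd, linear falloff to
0 at mean ± 3 sd; without an experimental corridor the bands default to 5%
and 50% of the reference peak amplitude), and cross-correlation sub-ratings
for phase (lag of the maximal correlation within ±20% of the duration),
size (absolute-area ratio) and shape (correlation at the optimal lag,
clipped to [0, 1]); combined = 0.5 corridor + 0.5 mean(size, phase, shape).
Ties in the lag scan resolve to the smallest |lag|; components within 1e-12
of 1 are snapped to exactly 1 so that self-rating is exact; a candidate with
no signal scores 0 on size/phase/shape. The decomposition and weights are
this package's documented choice — published CORA scores from other tools
are not comparable quantity-for-quantity.

## Synthetic data: what it emulates and what it does not

The fixture generators produce: the nine suction pulses (2/3/4 psi ×
25/50/100 ms, converted at 1 psi = 6.894757 kPa, half-cosine ramps over 10%
of the duration), a four-rate foam family with plateau-plus-densification
shape, the two drop configurations (6.15 and 4.54 m/s), and noisy replicate
corridors (Gaussian amplitude noise, optional timing jitter, fixed seed,
private RNG stream). These capture the *structure* of the experimental
inputs — rates, peaks, durations, replicate scatter — but not their
idiosyncrasies: real suction pulses are not ideal trapezoids, real foam
curves carry measurement noise and batch variation, and real kinematic
replicates differ in shape as well as amplitude. Passing tests therefore
demonstrate correctness of the implemented laws and metrics under the
stated study conditions, not biofidelity of any particular animal dataset.

## Problem sizes and tolerances used in the tests

Oracle equivalence uses 100 random deformation gradients at 1e-6 relative;
frame indifference 20 random rotations at 1e-10; the Prony recursion is
checked against a hereditary-integral quadrature on a 0.002 ms grid
(relative error bound 0.5%, plus a convergence check under step halving).
The impact property suite runs the two default drops, the six-case angle
sweep, the three-case stiffness sweep and one half-step convergence run at
the default `dt = 0.001 ms`; corridor convergence uses 200 replicates
against the 3 sd/sqrt(n) law-of-large-numbers bound. These sizes keep the
full suite around two minutes on a single core while leaving each check
statistically meaningful.

## Known limitations

* The planar impact model cannot represent out-of-plane rotation; sideways
  cases are bookkeeping approximations.
* Skull deformability enters only through the contact-stiffness scale;
  intracranial strain fields (the full model's MPS/MPSR maps) are out of
  scope.
* Absolute peak magnitudes depend on stand-in inertia/neck/foam parameters
  and are not calibrated to any specific dataset; only anchors, signs,
  orderings and timings are claimed.
* The fiber material's Prony constants and all tissue densities are
  documented stand-ins pending tabulated values.
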