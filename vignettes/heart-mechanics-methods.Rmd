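---
title: "Methods: stabilized mixed FE heart-wall mechanics coupled to a closed-loop circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stabilized mixed FE heart-wall mechanics coupled to a closed-loop circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(heartfem)
```

`heartfem` simulates the beating heart as a quasi-static nonlinear
finite-element model of the muscular wall, exchanging pressures and volumes
with a closed-loop lumped-parameter (0D) model of the systemic and pulmonary
circulations at every timestep.  This vignette documents the model, its
assumptions, the tunable parameters, the numerical choices, and what the
idealized fixtures do and do not demonstrate about real hearts.

## Tissue model

The wall is an incompressible, transversely isotropic hyperelastic solid.
The first Piola–Kirchhoff stress decomposes additively into passive and
active parts, plus the incompressibility pressure:

$$\mathbf P = \frac{\partial W}{\partial \mathbf F} + \mathbf P_{act}
  - p J \mathbf F^{-T}.$$

**Passive law.** A Fung-type exponential energy
$W = \tfrac{C}{2}\,(e^{Q} - 1)$ with
$Q = b_{ff}E_{ff}^2 + b_{xx}(E_{ss}^2 + E_{nn}^2 + E_{sn}^2 + E_{ns}^2) +
b_{fx}(E_{fn}^2 + E_{nf}^2 + E_{fs}^2 + E_{sf}^2)$, where $E_{ij}$ are
Green–Lagrange strain components in the local fiber/sheet/sheet-normal
triad.  Defaults (`passive_params()`): $C = 130$ kPa, $b_{ff} = 29.0$,
$b_{xx} = 26.6$, $b_{fx} = 13.3$.

A note on magnitudes: a stiffness scale of 130 kPa (and a peak tension of
700 kPa, below) is two to three orders of magnitude above the values this
law family is usually fitted with ($C \sim 0.1$–$0.5$ kPa,
$T_{ref} \sim 70$–$150$ kPa), which suggests these reference values
may carry a Pa/kPa units slip.  The package deliberately does **not**
rescale them: they are plain configuration entries, adopted verbatim as
defaults, and every verification test is parameter-independent or supplies
its own material.  The practical consequence on the bundled fixtures is a
very stiff chamber (diastolic compliance of order $10^{-2}$ mL/mmHg), so
the idealized ventricle operates almost isovolumetrically with a small
ejection fraction; all coupled-physiology checks on the fixtures are
therefore directional (signs and orderings), never magnitudes.

**Active stress.** Tension acts along the deformed fiber direction,

$$\mathbf P_{act} = T_{ref}\,
  \frac{Ca_0^2}{Ca_0^2 + ECa_{50}^2(l)}\; C_t(t)\;
  \mathbf e_f \otimes \mathbf e_{f0},
  \qquad ECa_{50}(l) = \frac{(Ca_0)_{max}}{\sqrt{e^{B(l-l_0)} - 1}},$$

with temporal activation $C_t(t)$ a raised-cosine upstroke to time $t_0$
followed by exponential relaxation after $t_t$ with constant $\tau$
(`temporal_activation()`).  Defaults: $T_{ref} = 700$ kPa, $Ca_0 =
(Ca_0)_{max} = 4.35\ \mu M$, $B = 4.75\ \mu m^{-1}$, $l_0 = 1.58\ \mu m$,
$t_0 = 275$ ms, $t_t = 300$ ms, $\tau = 25$ ms, cycle length 800 ms.

Two points the tension law leaves open were decided as follows:

* **Sarcomere-length map.** The current sarcomere length is taken as
  $l = l_{ref}\,\lambda_f$ with $\lambda_f = |\mathbf F\,\mathbf e_{f0}|$
  the fiber stretch and $l_{ref} = 1.85\ \mu m$ a typical unloaded
  sarcomere length (configurable).  This is the minimal map consistent
  with "current and resting sarcomere lengths" and gives the tissue a
  shortening capacity of about 15% before the calcium gate closes —
  the property that self-limits ejection.
* **Below resting length** the gate expression is imaginary; the gate is
  defined as 0 for $l \le l_0$ (tension can be neither negative nor
  complex), with a continuous transition (the gate and its value tend to 0
  as $l \downarrow l_0$).
* **Atrial activation** uses the same law with a late-diastolic onset
  (720 ms by default, i.e. the atrial kick precedes the next ventricular
  beat) and chamber-specific timing; no separate atrial tension law is
  published with the ventricular parameter set, so atrial contractility is
  an ordinary configurable.

## Weak form and discretization

Quasi-static momentum balance plus incompressibility, both in the reference
configuration: find $(\mathbf u, p)$ with

$$0 = \int_{\Omega_0} (\mathbf P - pJ\mathbf F^{-T}) : \nabla \delta\mathbf u
 \, dV - \int_{\Omega_0} \delta p (J - 1)\, dV
 + \int_{\Gamma_{epi}} (\mathbf K_{epi}\mathbf u + \mathbf C_{epi}\dot{\mathbf u})
 \cdot \delta\mathbf u \, dS
 - \sum_{ch} P_{ch} \int_{\Gamma_{endo}^{ch}} J \mathbf F^{-T}\mathbf N
 \cdot \delta \mathbf u \, dS.$$

* Linear tetrahedra with equal-order (P1–P1) displacement/pressure
  interpolation and one quadrature point per element.
* **Pressure stabilization**: the incompressibility equation is augmented
  with $\sum_e \frac{\alpha h_e^2}{2\mu} \int_e \nabla p \cdot \nabla
  \delta p\, dV$ ($\alpha = 1$ by default, $h_e$ = longest element edge,
  both configurable).  The shear scale defaults to $\mu = C\,b_{xx}/2$,
  the small-strain shear stiffness of the passive law; stabilization needs
  only order-of-magnitude correctness in $\mu$.  Without this term the
  equal-order pair is singular — the test suite demonstrates both the
  failure at $\alpha = 0$ and the smooth pressure field at $\alpha = 1$.
* **Robin epicardial condition** (pericardial restraint):
  $\mathbf K_{epi} = k_n \mathbf N\otimes\mathbf N + k_t(\mathbf I -
  \mathbf N \otimes \mathbf N)$ and likewise $\mathbf C_{epi}$, evaluated
  with reference normals; velocity is discretized backward-Euler
  $(\mathbf u - \mathbf u_{prev})/\Delta t$, so damping enters the tangent
  as $\mathbf C_{epi}/\Delta t$.  No published coefficient values exist
  for this condition; the defaults ($k_n = 0.5$, $k_t = 0.02$ kPa/mm,
  $c_n = 2$, $c_t = 0.1$ kPa·ms/mm) were calibrated once on the ellipsoid
  fixture for small radial epicardial motion with free tangential sliding.
* **Dirichlet condition**: the flat basal annulus of the fixtures (the
  stand-in for the truncated great-vessel rims) is fixed.  With the Robin
  terms active the model is solvable even without any Dirichlet patch (the
  suite checks the six rigid modes disappear).
* The cavity pressure is a follower load integrated on the deformed
  endocardium, with its exact (nonsymmetric) tangent.
* **Newton solver** with the analytic consistent tangent (material,
  geometric, active, pressure-coupling and follower-load blocks) and
  sparse LU; convergence at relative 1e-8 / absolute 1e-10 on the residual
  norm, with two pragmatic guards: load continuation (pressure bisection)
  on failure, and acceptance of residuals stalled at the floating-point
  assembly floor when they are at least $10^5\times$ below the initial
  residual.  The inner solves driven by the coupling loop reuse the
  factorized tangent while the residual contracts fast (modified Newton);
  verification tests always use full Newton.
* The reference configuration is treated as stress-free; no inverse
  (unloading) problem is solved.

## Fibers and fixtures

Meshes are generated structurally on truncated prolate spheroids
(`make_truncated_ellipsoid_mesh()`): a parametric grid in transmural,
longitudinal and circumferential coordinates whose cells are split into
tetrahedra via cell centroids, with quad-face diagonals chosen through the
global minimum vertex index — a rule that makes the triangulation of shared
faces identical in adjacent cells, so the mesh is conforming including at
the degenerate apex.  Surface patches `endo`, `epi`, `base` label the
boundary; the truncation plane is the chamber's cap plane for
divergence-theorem cavity volumes.

The transmural coordinate solves a Laplace problem (0 at endo, 1 at epi).
Ventricular fibers follow the linear transmural helix rule, +60° at the
endocardium to −60° at the epicardium by default, in the local
circumferential–longitudinal plane; the sheet direction is the normalized
transmural gradient and the sheet normal completes the right-handed triad.
The helix rule specifies only the fiber direction, not the sheet field the
anisotropy exponents act on, so the transmural-sheet convention here is a
documented package choice.  Near the apex the circumferential direction degenerates and an
arbitrary perpendicular is used (logged).  Atrial fibers use a
single-parameter circumferential/longitudinal blend
(`assign_atrial_fibers()`) instead of anatomically labeled atrial
architecture: chamber-level PV physiology is insensitive to the fine
atrial fiber map, which is all the fixtures exercise.

## Closed-loop circulation and coupling

The 0D loop (`circ_params()`, `circ_step()`) has four linear-compliance
vascular compartments (systemic/pulmonary, arterial/venous) with series
resistances, four ideal-diode valves, and no inertances, venous valves, or
reflex control.  Volumes advance by explicit Euler updates (internally
substepped to ≤1 ms) with chamber pressures held at their new-time values —
the semi-implicit element of the scheme; total blood volume is conserved
exactly by construction.  No authoritative parameter table exists for
this particular loop, so the defaults were calibrated once
against the elastance-surrogate configuration to an ordinary adult
operating point (LV ≈ 134/58 mL, SV ≈ 76 mL, peak LV pressure ≈ 126 mmHg,
RV peak ≈ 25 mmHg at an 800 ms cycle) and are exposed in full.

Chambers not resolved in 3D run as time-varying elastance surrogates
(`elastance_chamber_pressure()`), sharing the temporal activation shape.

**Coupling.**  At each step the driver finds chamber pressures $P^*$ such
that the FE cavity volumes at $P^*$ equal the 0D chamber volumes after a
circulation step driven by $P^*$: the residual
$R_{ch}(P) = V_{FE}^{ch}(P) - V_{circ}^{ch}(P)$ is reduced below
$10^{-4}$ mL (the residual is a volume difference, so the tolerance is
interpreted in volume units).  With several 3D
chambers a quasi-Newton (Broyden) iteration with a finite-difference
Jacobian (1e-3 mmHg perturbations) is used, warm-started from the previous
step.  With a single 3D chamber the residual is scalar, monotone in $P$,
but kinked where valves open or close; the driver brackets the root and
uses Illinois-modified regula falsi, seeding the bracket with the known
kink candidates (the neighboring chamber and arterial pressures).  On
stagnation the timestep is bisected.  The mmHg↔kPa conversion
(1 mmHg = 0.1333 kPa) is applied exactly once, at this boundary.

Within a step the FE volumes are evaluated at the trial pressures and the
circulation is stepped with the same trial pressures; the root finder
enforces the fixed-point consistency; the operator ordering within a step
is a package design choice.  The 0D state keeps its own (exactly
conservative) chamber volumes, so conservation does not degrade with the
number of coupling iterations.

`run_cardiac_cycles()` advances cycle by cycle and declares a time-periodic
steady state when every chamber's end-diastolic volume changes by less
than 0.5% between consecutive cycles; end-diastolic volume is the natural
per-cycle summary for this criterion.
With zero 3D chambers the driver reduces exactly — bit-compatibly — to
`run_0d_only()`.

## Strains and outputs

Strain waveforms use directional stretches
$\lambda = \sqrt{\mathbf e \cdot \mathbf C \mathbf e}$ along per-element
longitudinal and circumferential unit vectors (built from the same
apex–base frame as the fiber rule), expressed relative to the
end-diastolic configuration (detected as the maximum-LV-volume snapshot)
and converted to directional Euler–Almansi strain
$\varepsilon = \tfrac12(1 - \lambda^{-2}) \times 100\%$.  Global waveforms
are wall-volume-weighted means over the elements; they are zero at
end-diastole by construction, and systolic shortening is negative (peaks
are reported as peak absolute values).  PV metrics are EDV = max V,
ESV = min V, SV, EF, peak P.  Atrial figure-of-eight loops are detected by
locating the self-intersection of the PV polyline and splitting it into
A- and V-loops with signed (shoelace) areas.

## Problem sizes and verification scope

The package verifies itself at desk scale:

* Constitutive worked values against independent scalar arithmetic.
* The assembled tangent against central finite differences (all terms).
* Homogeneous uniaxial incompressible stretch against the semi-analytic
  Fung solution (exact for the discrete space, so agreement is to machine
  precision).
* Stabilized P1–P1 inflation of a thick hemispherical shell against the
  classical semi-analytic incompressible sphere-inflation solution (1D
  quadrature of the through-wall stress difference) with isotropized
  exponents ($b_{ff} = b_{xx} = b_{fx}$ makes $Q$ frame-invariant): the
  discretization error decreases under refinement (about 5% → 2% between
  ~4k and ~17k elements in the development runs).  This closed-form route
  replaces a same-codebase higher-order element as the reference: it is
  independent of every code path it checks.
* The coupled fixture: one 3D left ventricle (~800 elements, Δt = 4 ms,
  5 cycles) against the coupling tolerance, exact blood-volume
  conservation, and the all-surrogate equivalence; a 25% LV-contractility
  case checks the directional physiology (lower LV peak pressure and EF).
  Because the verbatim stiffness defaults make the fixture's cardiac
  output small, the circulation is still settling over these cycles;
  baseline and reduced-contractility runs are therefore compared at the
  same cycle index, which isolates the contractility effect from the
  slow loop transient.

These sizes are the package's own verification choices; finer meshes and
Δt = 1 ms are plain configuration.

What the fixtures do **not** show: patient-specific anatomy (a truncated
spheroid has no septum, outflow tracts or valve annuli, hence no
ventricular interdependence through a shared wall — on the fixture the
interdependence is purely circulatory), realistic diastolic compliance
under the verbatim stiffness defaults (see the units note above),
valve leaflet dynamics or intracavitary flow, viscoelastic or
history-dependent tissue behavior, and electrophysiologically realistic
activation sequences (activation is synchronous per chamber).

## Degenerate inputs and tie-breaks

Inverted elements ($J \le 0$ at a quadrature point) abort the Newton step
with a diagnostic and trigger continuation.  Strain-energy exponents
$Q > 250$ raise an overflow error rather than returning `Inf`.  Meshes are
validated on construction (positive orientation, watertight patch cover,
outward orientation).  Empty Dirichlet patches warn and leave the model
restrained only by the Robin terms.  The apex fiber fallback and the
valve-corner seeding of the coupling root finder are described above.
Random numbers appear only in the optional jittered initial guess
(`simulation_config(seed = )`); all default runs are deterministic, and
identical configurations reproduce records bit-compatibly.
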