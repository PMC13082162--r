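# heartfem

Finite-element simulation of beating-heart mechanics coupled to a
closed-loop model of the systemic and pulmonary circulations, in R.

Whole-heart mechanics models answer questions that isolated-chamber models
cannot: how a change in one chamber's contractility propagates to the
others through the shared circulation, how atrial contraction shapes
ventricular filling ("atrial kick"), and how pericardial restraint shapes
wall motion. `heartfem` implements the full simulation chain for such
studies — tissue model, stabilized mixed finite elements, boundary
conditions, a lumped-parameter circulation, bidirectional 3D–0D coupling,
and clinical-style outputs (pressure–volume loops, ejection fractions,
myocardial strain waveforms) — together with idealized chamber-geometry
generators so that the entire method is testable without any external
anatomy download.

## The model in brief

The myocardium is an incompressible, transversely isotropic hyperelastic
solid. The first Piola–Kirchhoff stress is

**P** = ∂W/∂**F** + **P**<sub>act</sub> − p J **F**<sup>−T</sup>,

with a Fung-type passive energy W = (C/2)(e<sup>Q</sup> − 1), where Q is a
quadratic form in the Green–Lagrange strain components expressed in the
local fiber/sheet/sheet-normal triad, and an active fiber tension

**P**<sub>act</sub> = T<sub>ref</sub> · Ca₀²/(Ca₀² + ECa₅₀²(l)) · C<sub>t</sub>(t) · **e**<sub>f</sub> ⊗ **e**<sub>f0</sub>,

whose calcium sensitivity depends on sarcomere length l (Frank–Starling)
and whose time course C<sub>t</sub>(t) is a raised-cosine upstroke with
exponential relaxation. The weak form is discretized with equal-order
linear tetrahedra (P1–P1) and a residual-based pressure-Laplacian
stabilization Σ<sub>e</sub> (α h<sub>e</sub>²/2μ) ∫ ∇p·∇δp dV; the
epicardium carries an anisotropic Robin spring–damper (stiff radially,
nearly free tangentially, mimicking the pericardium); cavity pressures are
follower loads on the endocardium. A four-compartment, four-valve
closed-loop 0D circulation supplies chamber pressures; at every timestep a
root finder adjusts them until the FE cavity volumes match the 0D chamber
volumes, ‖**R**‖ < 10⁻⁴ mL. Ventricular fibers follow the rule-based
+60°/−60° transmural helix on a harmonic transmural coordinate. Chambers
not resolved in 3D run as time-varying elastance surrogates.

See `vignettes/heart-mechanics-methods.Rmd` for the full model account,
parameter tables, design decisions and limitations.

## Worked example

A pure-0D run (all four chambers as elastance surrogates), then a coupled
run with a 3D finite-element left ventricle on the bundled
truncated-ellipsoid fixture:

```r
library(heartfem)

rec <- run_0d_only(cycles = 12)          # reaches periodic steady state
print(last_cycle(rec))
#> beat_record: 800 steps, t in [ 8801 , 9600 ] ms
#>   LV: EDV 133.9  ESV 57.9  SV 76.0 mL  EF 56.7%  peak P 126.5 mmHg
#>   RV: EDV 130.1  ESV 54.0  SV 76.0 mL  EF 58.5%  peak P 25.2 mmHg
#>   LA: EDV 64.7  ESV 27.6  SV 37.1 mL  EF 57.3%  peak P 11.0 mmHg
#>   RA: EDV 49.0  ESV 19.6  SV 29.4 mL  EF 60.1%  peak P 6.2 mmHg

detect_atrial_figure8(last_cycle(rec), "la")$crossing_found
#> [1] TRUE     # the atrial PV loop shows the physiologic figure-of-eight

mesh   <- make_truncated_ellipsoid_mesh(ellipsoid_spec(target_edge = 8))
fibers <- assign_ventricular_fibers(mesh)      # +60/-60 transmural helix
cfg    <- simulation_config(mesh = mesh, fibers = fibers,
                            chambers_3d = "lv", dt = 4, n_cycles = 5)
run    <- run_cardiac_cycles(cfg)
max(run$coupling)                     # largest 3D-0D volume residual (mL)
#> [1] 9.995172e-05
unlist(pv_metrics(run$final_cycle, "lv"))
#>       EDV       ESV        SV        EF     peakP
#> 76.896792 70.785866  6.110926  7.946920 34.881882
```

The first block's numbers are what the calibrated default circulation
produces — an ordinary adult operating point (LV stroke volume 76 mL,
ejection fraction 57%, peak pressure 127 mmHg). In the coupled block the
fixture ventricle uses the reference constitutive defaults verbatim
(C = 130 kPa, T_ref = 700 kPa); these are orders of magnitude stiffer than
typical fits of this law, so the idealized chamber ejects little — the
coupled fixture is a numerics testbed (residuals, conservation,
directional physiology), not a calibrated healthy ventricle. The methods
vignette discusses this openly.

An ischemia protocol scales one chamber's contractility:

```r
run25 <- run_cardiac_cycles(apply_ischemia(cfg, "lv", 0.25))
pv_metrics(run25$final_cycle, "lv")$peakP < pv_metrics(run$final_cycle, "lv")$peakP
#> [1] TRUE
```

A command-line wrapper is installed at `inst/scripts/simulate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/simulate.R", package="heartfem"))')" \
  --chambers lv --cycles 5 --dt 4 --ischemia lv:0.25 --out run_out
```

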