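---
title: "Cycle-to-cycle cardiac FSI coupling: models, numerics, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-to-cycle cardiac FSI coupling: models, numerics, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cardioloop` implements a sequential, cycle-to-cycle coupling between a
cardiac wall-mechanics stage and an intraventricular flow stage on an
idealized two-dimensional left ventricle. This vignette documents the
models, the numerical methods, the parameters that matter, and the
design decisions taken where the problem left genuine freedom. It
states no empirical result that the test suite and the acceptance
script do not themselves compute.

## 1. The coupled problem

Whole-heart mechanics models commonly obtain chamber pressures from a
lumped circulation, so the load on the endocardium is spatially
uniform at every instant. Resolved chamber flow, on the other hand,
produces local wall-pressure deviations of a few percent of the
chamber pressure, concentrated where jets impinge (outflow tract in
systole, apex during filling). The coupling studied here communicates
exactly this information, once per heart cycle:

* mechanics → fluid: the last-cycle endocardial wall motion and the
  inlet/outlet pressure traces;
* fluid → mechanics: a dimensionless, spatially resolved, *mean-free*
  pressure factor per wall element and cycle phase.

With per-time statistics `p_min`, `p_max`, `p_mean` of the
wall-element pressures of one chamber, the time-resolved scaling
factor is `y_s = 2 (p_max - p_mean) / p_max`, clipped to `[-3, 3]`,
and the factor field is
`x_i = y_s (p_i - p_mean) / (p_max - p_min) + 1`. Its element mean is
one by construction, so multiplying the circulation's chamber pressure
by `x_i` redistributes the load without biasing the circulation. Two
degenerate cases need conventions the problem statement leaves open:
a spatially uniform field maps to `x = 1` (it carries no spatial
information), and `p_max = 0` maps to `y_s = 0`. Both preserve the
mean-free property and make a uniform-pressure fluid stage an exact
fixed point of the loop, which the test suite checks bitwise.

A known algebraic subtlety: reconstructing the fluid pressure exactly
from `x_i p_mean` would require the scaling `(p_max - p_min)/p_mean`
rather than the definition above; the implementation follows the
stated definition and does not attempt reconstruction.

Convergence is judged by the Euclidean distance (ED) between
corresponding wall nodes of successive mechanics runs, summarized as
min/max/mean in mm over the last cycle; iteration stops below
`tol_mm` (default 0.1 mm, two decades below the chamber radius scale)
or after `max_iter` (default 3) iterations.

### The pressure-factor determination window

Applied naively, the loop on this desk-scale model *amplifies*: the
raw wall-pressure field contains sharp systolic transients, the factor
turns them into an impulsive load on the wall solver, the next fluid
run sees an even sharper wall motion, and the maximum ED grows from
iteration to iteration. The remedy — anticipated in the literature on
this scheme as a "time window" for the scaling-factor determination —
is to smooth each element's pressure trace with a periodic moving
average before the statistics are taken
(`coupling$pf_time_window`, default 0.125 s ≈ 10% of the cycle).
With the window in place the loop contracts by roughly an order of
magnitude per iteration on the default preset (measured by the
acceptance suite); without it (`pf_time_window = 0`) the divergence is
reproducible. The window trades temporal sharpness of the feedback for
the contractivity of the fixed-point iteration; the spatial structure
of the factor is untouched.

The factor is applied in the final mechanics cycle only
(`pf_window = "last"`); `"all"` applies it throughout and leads to the
same contraction behavior, so the choice is kept at the literal
single-cycle reading with the alternative behind the switch.

## 2. Wall mechanics stage

Each of the `n_seg + 1` wall nodes moves radially about the base
center (this keeps the two base corners on the valve plane). The force
balance per unit wall area is

    rho0 h0 a_i = (p_i - p_ext) - (T_pass(lambda_i) + T_act(t)) / r_i
                  + kappa r0_i lap(lambda)_i - c_damp v_i

with `lambda_i = r_i / r0_i` the circumferential stretch and
Laplace-law conversion of tension to pressure.

* **Passive tension.** The Guccione strain-energy law
  `W = C/2 (e^Q - 1) + K/2 (J-1)^2` with
  `Q = b_f E11^2 + b_t (E22^2 + E33^2 + E23^2 + E32^2) + b_ft (...)`,
  reduced to membrane kinematics `E11 = (lambda^2-1)/2`, `E22 = 0`,
  `E33 = (lambda^-2-1)/2`, `J = 1`;
  `T = h lambda dW/dlambda`, differentiated analytically and verified
  against a central finite difference of the energy to 1e-5 relative.
  Parameters are the published ventricular row (`C = 278` Pa,
  `b_f = 12.0`, `b_t = 4.8`, `b_ft = 8.4`, `K = 200` kPa,
  `rho0 = 1082` kg/m^3); the atrial, vessel, fat, pericardial and
  valve-plane Neo-Hookean rows are carried as presets. The Neo-Hookean
  energy uses the isochoric split
  `W = C/2 (Ibar1 - 3) + K/2 (J-1)^2` — the exact variant used by the
  reference chain is not published; this one is consistent with the
  printed volumetric penalty.
* **Active tension.** A periodic double-Hill driver
  `a(tau) = h T_peak g1(tau) g2(tau)`,
  `g1 = (tau/a1)^n1 / (1 + (tau/a1)^n1)`,
  `g2 = 1 / (1 + (tau/a2)^n2)`, period `T_cycle = 1.247` s. The shape
  parameters of the published model family (`a1 = 0.303`,
  `a2 = 0.508`, `n1 = 1.32`, `n2 = 21.9`) are defaults because the
  reference values are not printed; `T_peak = 80` kPa and
  `t_onset = 0.15` s were chosen once to give a physiological systole
  (peak chamber pressure near 60–80 mmHg against the reduced
  afterload) and are configurable.
* **Thickness grading.** The local wall thickness is
  `h_i = h0 r0_i / mean(r0)`. Under the Laplace law this makes the
  pressure a node's tension can carry independent of its reference
  radius — the membrane analogue of the curvature compensation a
  doubly curved shell provides. Without it the chamber is bimodal
  (soap-bubble instability): the apex balloons while the base corners
  collapse onto the compression-stabilized branch.
* **Shape regularization.** The neighbor term acts on the *stretch*
  field (`kappa r0 lap(lambda)`), not the raw radii: the reference
  radius profile of a half-ellipse has a nonzero discrete Laplacian,
  so a radius-based term would exert a spurious force at rest. The
  default `kappa = 2e7` Pa/m is set by two constraints: it must
  suppress the volume-neutral (soap-bubble) shape modes that the
  pressure feedback cannot stabilize, and its stiffness must stay
  inside the explicit RK4 stability region at `dt_mech = 1` ms.
* **Circulation.** A constant atrial preload (7.5 mmHg, the left-heart
  diastatic value), diode valves (`Q = max(dp, 0)/R`), and a
  two-element Windkessel afterload. The chamber pressure is enforced
  by a stiff artificial compliance
  `dp/dt = K_c (Q_mv - Q_ao - dV_wall/dt)/V` with `K_c = 1e8` Pa,
  integrated backward in time per valve regime (the piecewise-linear
  implicit equation is monotone and solved exactly by regime
  enumeration). Because the wall–pressure pair is stiff
  (`omega dt >> 1`), the backward update includes the wall's
  linearized pressure admittance and the resulting pressure increment
  is fed back into the wall velocities within the same step; this
  damps the stiff mode implicitly while the slow dynamics remain
  explicit RK4. The circulation parameters are reduced stand-ins
  tuned once for a classical pressure–volume loop, not published
  values.
* **Initial condition.** The wall starts at the passive equilibrium
  stretch under the preload (the diastatic configuration), found per
  node by bisection; starting from the unloaded reference would
  inflate violently and trip the 50 mmHg/step pressure guard.

The single most important correctness property — a factor field
identically one reproduces the uncoupled run *bitwise* — holds because
phase interpolation is written as `a + w (b - a)` and node averaging
as `(a + b)/2`, both exact for constant fields.

## 3. Fluid stage

A collocated finite-volume discretization on a boundary-fitted
polygonal grid: a "spider-web" of `n_r` rings over the closed chamber
boundary (triangles at the center, quadrilaterals elsewhere) with
structured tubes glued node-to-node on the inlet/outlet spans of the
base. The default grid is `n_r = 8` rings by 87 boundary segments
(64 wall + 23 base) plus the two tubes, about 950 cells — deliberately
small; the point is the coupling mechanism, not grid-converged
hemodynamics.

* **ALE transport.** Convective fluxes use the *relative* face flux
  `phi_f - s_f`, where `s_f` is the exact swept volume of the face
  between time levels divided by `dt`. Summed over a cell the swept
  volumes reproduce the cell volume change exactly (discrete geometric
  conservation law), so a uniform velocity field survives arbitrary
  interior mesh motion to machine precision — asserted at 1e-10 in the
  acceptance suite.
* **Projection.** Non-incremental (Chorin) splitting: the predictor
  carries convection, viscosity and the valve forcing but no pressure;
  a compact-stencil Poisson equation then determines the full pressure
  so the absolute face fluxes are divergence-free on the new mesh
  (below 1e-8 scaled, typically 1e-12). The Poisson coefficients use
  the over-relaxed non-orthogonality form `|S|^2 / (S . d)` (floored
  at `0.05 |S||d|` for near-degenerate deformed faces), and the
  factorization pattern is cached so each step costs one numeric
  Cholesky update. Cell velocities are corrected with a *weighted
  least-squares* gradient fitted to the compact face differences: on
  the high-aspect wedge cells at the web center a Green–Gauss gradient
  is inconsistent with the compact fluxes and destabilizes the
  scheme, while the least-squares gradient is exact for linear fields
  on arbitrarily anisotropic cells. (Rhie–Chow-type incremental
  variants were tried and rejected for the same reason.)
* **Valves.** The Darcy–Forchheimer forcing
  `F = -(phi mu)/(rho k L^2) u_rel - 1.75 phi / sqrt(150 k L^2) |u_rel| u_rel`
  acts in a porous zone of depth 5 mm at the mouth of each tube, with
  `L_ref` equal to that depth converting the dimensionless
  permeability `k` to a dimensional one. `k` follows the
  flux-magnitude ramp (blocked `1e-7` below 20 ml/s, 1 above
  160 ml/s, linear between, the same curve for opening and closure —
  no hysteresis, one reading of an ambiguous description). The zone's
  volume-flux signal is the chamber volume rate from the moving mesh;
  the mitral zone responds to filling, the aortic to ejection. The
  forcing is applied as a pointwise semi-implicit relaxation toward
  the plane motion, and — essential — the same relaxation factor
  scales the pressure-Poisson coefficients of the zone's faces
  (harmonic mean across a face), so a blocked plane is impermeable to
  the projection fluxes too, leaving only the physical Darcy leak.
  Blocked faces flux like moving walls and are treated as
  zero-gradient faces by the cell-gradient fit.
* **Time stepping.** `dt` starts at 1 ms and follows the convective
  Courant bound `CFL <= 0.7` with an inradius-like cell size
  `2V/P`, the growth clamp `1.2 dt_prev`, a 2.5 ms cap resolving the
  wall-motion interpolation, *and* the explicit-diffusion stability
  limit `0.5 min(V / sum nu |S|/d)` recomputed from the current
  geometry — the wedge cells at the web center make the viscous limit
  the binding one on this grid.
* **Washout scalar.** First-order upwind on the corrected relative
  fluxes: bounded in `[0, 1]` under the CFL bound and exactly
  conservative (boundedness over accuracy; the physical diffusivity
  `1e-10 m^2/s` is a stability token only). The scalar starts at 1 in
  the chamber and 0 in the tubes; `residual_volume()` integrates it
  over the chamber in ml.
* **Wall motion replay.** The mechanics motion is interpolated
  periodically in phase and blended to zero over `pi/16` of boundary
  parameter at the two base corners, anchoring the valve plane (the
  analogue of the rigid trunk region); mesh motion solves a graph
  Laplacian with inverse-squared wall-distance diffusivity (floor
  1 mm), factorized once, hence exactly linear in the boundary data.

Verification: steady Poiseuille flow in a static channel matches the
closed-form parabola within 2% at 32 cells across; the global mass
balance (net port outflow against mesh volume change) holds to 1e-6
relative; four replayed cycles approach a periodic limit cycle
(cycle 3→4 wall-pressure distance below cycle 1→2).

## 4. What the synthetic generators emulate

`make_synthetic_pressure_field()` produces seeded wall-pressure fields
with a smooth diastolic/systolic mean trace plus localized bumps —
an outflow-tract jet in systole (`"outlet-jet"`), an apex bump during
early filling (`"apex-jet"`), plain Gaussian noise, or a spatially
uniform field. These reproduce the *structure* that resolved chamber
flow imprints on the wall (dominant mean, percent-scale localized
deviations) and are used to exercise the factor pipeline at scale.
They do not emulate vortex dynamics, wall-shear patterns, or
beat-to-beat variability. `make_synthetic_wall_motion()` provides an
analytic radially contracting chamber for running the fluid stage
stand-alone. Passing tests on these fixtures validates the coupling
arithmetic and the solvers' conservation structure, not the clinical
realism of any particular flow field.

## 5. Problem sizes and known limitations

The default study conditions are 64 wall segments, an 8-ring grid
(about 950 cells with the tubes), 10 mechanics cycles, 4 fluid cycles
and up to 3 coupled iterations; the whole loop is a couple of minutes
of single-core compute, and the acceptance suite runs the full
protocol unreduced.

Limitations worth keeping in mind:

* Two-dimensional, unit depth: "volumes" are areas times 1 m, hence
  litre-scale numbers; out-of-plane vortex dynamics are absent, so
  washout rates are qualitative.
* The wall model has one radial degree of freedom per node — no
  bending, no axial motion of the base, no atrial contraction, no
  pericardial contact; fiber anisotropy enters only through an
  optional blend of the Guccione exponents.
* The mean-pressure neutrality of the coupled dynamics is a
  small-perturbation property: the mean chamber-pressure trace
  responds superlinearly to the factor amplitude through diode-valve
  switching. At the amplitudes the converged loop operates at
  (`|x - 1|` of order 1%), the cycle-averaged trace shifts by well
  under 1%.
* The quantile convention of the factor bands is linear interpolation
  of order statistics (type 7); ED tables are reported in mm.
* The fluid stage is first-order in time and space by design
  (robustness on a moving polygonal grid); quantitative hemodynamic
  indices would need a finer grid and a higher-order scheme.
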