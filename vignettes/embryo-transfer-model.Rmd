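---
title: "Modelling intrauterine mixing flow and embryo transport during embryo transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intrauterine mixing flow and embryo transport during embryo transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(etflow)
```

## The problem

Embryo transfer (ET) is the final step of in-vitro fertilization: a
transcervical catheter loaded with a few microlitres of transfer medium and
the embryos is advanced into the uterine cavity, the load is injected, and
the catheter is withdrawn. Where the embryos end up — near the fundus
(favourable), in the lower cavity, or dragged back into the cervical canal —
is decided by the short-lived flow that the injection and the withdrawal
drive in the intrauterine fluid. Because the embryos cannot propel
themselves, their delivery sites are a pure fluid-mechanics question, and
one that is essentially impossible to observe in vivo.

`etflow` simulates this process: a two-dimensional incompressible laminar
flow of the transfer-medium/uterine-fluid mixture in a half-symmetric
uterine-cavity geometry, one-way coupled to a Lagrangian tracker for ten
embryos. The two fluids differ strongly in viscosity — uterine fluid is
glycerin-like (0.799 Pa s) while normal saline is 0.001 Pa s — and the
package's central scientific question is how that contrast shapes the
dispersion pattern of the medium and the embryo delivery sites.

## Geometry

The mid-sagittal section of an average-sized uterus is idealized as a
triangle (base 32 mm across the fundus, height 50 mm) joined to a straight
cervical channel (25 mm long, 4 mm wide, ending at the external ostium). A
catheter of 0.6/0.8 mm inner/outer diameter lies along the midline with its
tip 15 mm from the fundus; two 0.3 mm openings at the lateral ends of the
fundal base stand for the fallopian-tube ostia. Flow and geometry are
symmetric about the midline, so only the upper half is computed, with a
symmetry condition on the axis:

```{r}
g <- uterus_geometry()
g$tip_x          # 60 mm from the external ostium
geometry_area(g) # continuum half-domain fluid area, mm^2
```

The triangle apex has zero width where it meets the 4 mm cervix; we resolve
this (the drawing does not dimension it) by carrying the 2 mm cervical
half-width into the cavity until the slanted wall takes over, i.e.
`Y(x) = max(2, 0.32 (x - 25))` mm. The tube ostium is placed at the lateral
end of the fundal base. Both choices are documented conventions rather than
inferred intent.

## Mixture flow model

Both fluids are incompressible and miscible, the injection Reynolds number
is of order 10, and the injection is too short for diffusion between the
fluids to matter. The mixture is therefore described by a single velocity
field `u_m` shared by both fluids (a homogeneous multiphase model), with
composition tracked by the transferred-medium volume fraction `alpha`:

* mass: `d(rho_m)/dt + div(rho_m u_m) = 0`
* momentum: `d(rho_m u_m)/dt + div(rho_m u_m u_m) = -grad p +
  div(mu_m (grad u_m + grad u_m^T))`
* composition: `d(alpha rho_1)/dt + div(alpha rho_1 u_m) = 0`
* closure: `rho_m = alpha rho_1 + (1-alpha) rho_2`,
  `mu_m = alpha mu_1 + (1-alpha) mu_2`

With constant phase densities the mass equation reduces to `div(u_m) = 0`,
which is what the pressure solver enforces; the momentum equation keeps the
variable mixture density. The stress term is implemented in the standard
variable-viscosity form `div(mu_m (grad u + grad u^T))`.

Boundary conditions: no-slip/no-penetration on all walls; a constant
(zero-gauge) pressure outflow at the external ostium and at the tube
ostium; a constant plug velocity at the catheter-bore entrance during
injection, computed from the transferred volume and injection time over the
circular bore area (`inlet_velocity()`; 20 uL in 1 s through a 0.6 mm bore
gives 70.7 mm/s); and moving-wall conditions on the catheter during
withdrawal (below). A parabolic inlet shape is available
(`inlet_profile = "parabolic"`) but the plug default is adequate: the bore
is two orders of magnitude longer than the entrance length at these
Reynolds numbers, so the profile develops internally either way.

### Planar and axisymmetric metrics

The domain is planar (a sagittal section). The solver nevertheless supports
an axisymmetric metric about the catheter axis (`metric = "axisymmetric"`),
which is useful for validating the bore hydraulics against pipe Poiseuille
flow; the planar metric is validated against plane Poiseuille flow. All
volumetric bookkeeping is internally consistent within a metric. The
injection driving force is always reported as the area-mean inlet gauge
pressure times the circular bore area `pi r_c^2` — the only convention
that gives forces in newtons at the magnitudes practitioners quote — with a
per-unit-depth planar variant included for transparency.

## Numerics

The equations are discretized with a cell-centered finite-volume method on
a non-uniform rectilinear grid. The triangular walls and the catheter are
represented by stair-step solid blanking, which turns catheter motion into
a time-dependent mask instead of a moving mesh; grid lines are aligned with
the bore radius, the wall annulus, the cervical half-width and the
tube-ostium band, and the region around the catheter tip is refined.
Convection uses first-order upwind differences and time stepping is
first-order implicit, the classical robust combination for this kind of
problem; both are monotone, at the price of numerical diffusion discussed
below. Pressure-velocity coupling uses the SIMPLE algorithm on the
colocated grid with Rhie-Chow momentum interpolation; momentum and pressure
under-relaxation default to 0.7 and 0.3 (larger factors destabilize the
impulsive start of injection). Within each time step the coefficient
matrices are assembled and factorized once and the SIMPLE sweeps update
only right-hand sides, which makes a sweep a handful of triangular solves.
Iteration stops when the summed continuity imbalance falls below a
tolerance relative to the driving boundary flux.

The volume fraction is advected implicitly with upwind fluxes taken from
the converged, divergence-consistent face velocities; implicit upwind is
monotone at any time step, and a final clip to [0, 1] guards round-off (the
clip magnitude is logged and is at machine precision in practice). The
global medium budget — initial bore content plus time-integrated inlet flux
minus outlet flux against the domain integral of `alpha` — closes to
round-off, and the test suite asserts it to better than 1%.

### Resolution profiles

Three bundled profiles set the mesh spacing and time steps
(`resolution_profile()`):

* `"coarse"` (default): about 2300 cells (bore resolved by 6 cells across
  the half-width, 0.5 mm axial cells near the tip, growing to 1.6 mm in the
  cavity); time step 2.5 ms during injection and 5 ms during withdrawal.
  All results quoted in the README use this profile; a full injection plus
  withdrawal run takes a few minutes on one core.
* `"mini"`: about 600 cells, 5-10 ms steps; used for fast checks and the
  cross-case trend tests.
* `"fine"`: 0.1-0.2 mm cells and the 0.1 ms time step; provided for
  convergence studies, at a few hours per case.

The implicit scheme is unconditionally stable, so the relaxed desk-scale
time steps trade only temporal resolution, not stability. The first-order
upwind scheme carries an effective numerical viscosity of order
`rho u h / 2`, which for the reference saline case is a few times
10^-2 Pa s in the jet region at coarse resolution: the low-viscosity cases
behave somewhat more viscous than nominal, compressing (but not reordering)
the differences among cases 1-3. This is the main accuracy limit of the
desk-scale profiles.

## Embryo dynamics

Embryos are rigid spheres (diameter 0.1 mm, density 1000 kg/m^3), so small
that their back-reaction on the flow is neglected; each of the ten embryos
is tracked independently. The only force retained is quasi-steady drag:

* `dv_e/dt = beta (u_m - v_e)` with
  `beta = 3 mu_m C_D Re_r / (16 rho_e r_e^2)`,
* `Re_r = 2 rho_m r_e |v_e - u_m| / mu_m`,
* `C_D(Re_r)` the Morsi-Alexander piecewise sphere-drag fit
  `a1 + a2/Re + a3/Re^2` (Stokes limit `24/Re` below `Re = 0.1`).

Gravity, buoyancy, lift, added mass and Brownian forces are excluded by
design. The `beta` prefactor `3/16` is the conventional sphere-drag
response, whose Stokes limit is `9 mu / (2 rho_e r_e^2)`; a `"doubled"`
form (prefactor `3/8`) is selectable because that variant also circulates
in the literature. The distinction is immaterial here: for every scenario
in this package `beta dt > 10^2`, the embryos relax to the local fluid
velocity within a fraction of a step (the tracer limit), and the test suite
asserts that delivery sites move by well under one cell when the form is
toggled.

Integrating `dv_e/dt = beta (u_m - v_e)` explicitly is unstable at
`beta dt >> 1`, so the stepper advances the velocity with the exact
exponential solution holding the sampled flow frozen over the step, and the
displacement by the trapezoidal rule on the velocity. Local flow properties
are sampled by bilinear interpolation between cell centers, with weights
restricted to fluid cells (no extrapolation through walls). An embryo that
numerically enters a solid cell is pushed back to the nearest fluid point
and the event is counted; converged runs log zero pushbacks away from the
wall-hugging withdrawal phase.

### Initial layout

The embryo's radial position in the catheter is unknown in practice, so the
bore cross-section is divided into ten equal-area zones (a central circle
and nine annuli) by circles of radius `r_i = sqrt(i/10) (r_c - r_e)`, and
one embryo starts at the radial midpoint of each zone, 10 mm behind the
tip, at rest. The ten zones stand for a uniform probability over the cross
section; the layout is deterministic, so identical configurations give
bit-identical trajectories.

## Catheter withdrawal

After injection the catheter is withdrawn toward the cervix for 5 s. The
withdrawal travel defaults to the catheter length inside the uterus plus
the cervical channel (81 mm), so the wall speed is 16.2 mm/s. Two
implementations are provided because the literature idiom and the physical
process differ, and the choice matters:

* `"sliding"` (default): the catheter geometry stays in place and its tip,
  inner and outer walls carry the withdrawal velocity as a moving-wall
  boundary condition for the whole 5 s (the velocity acts tangentially on
  the sliding faces; the bore entrance is a closed wall). This is exactly
  how a wall-velocity boundary condition behaves on a static mesh in
  standard CFD practice. It sustains the near-catheter Couette drag for
  the full withdrawal and is the mode that reproduces embryos being
  dragged many millimetres toward (and into) the cervical canal.
* `"translating"`: the catheter physically retracts as a time-dependent
  solid mask; vacated cells are uncovered and refilled, and the moving tip
  and plunger faces carry prescribed normal fluxes so the vacated volume
  is drawn in correctly. Here the tip passes any given embryo in a
  fraction of a second at 16.2 mm/s, so the cumulative drag is an order of
  magnitude smaller.

The two modes bracket the behaviour of a real, finite-speed withdrawal
with compliant walls; neither is a complete description. Drag-back
distances reported by `withdrawal_dragback()` are the mean axial
displacement toward the cervix between the end of injection and the end of
withdrawal, with counts of embryos ending in the cervical canal
(`x < 25` mm) and leaving through the external ostium.

## Post-processing metrics

* **Dispersion pattern** (`dispersion_pattern()`): the region with
  `alpha > 0.5`; its outline is extracted as the `alpha = 0.5` level set
  with linear interpolation on cell-center edges. The shape is classified
  by a documented heuristic: if more than 5% of the pattern area lies
  upstream of the tip (outside the catheter annulus) the pattern is an
  `"incomplete_ellipse"`, otherwise a `"sector"`. The threshold separates
  the two regimes cleanly at coarse resolution — low-viscosity cases have
  upstream fractions above 10%, equal-viscosity cases have exactly zero —
  so its precise value is not delicate.
* **Transport distances** (`transport_distances()`): per-embryo and mean
  axial (`x - 60` mm, positive toward the fundus) and radial (`|y|`)
  distances from the tip at the end of injection, with the
  upstream/downstream delivery region of each embryo (a position exactly
  on the tip plane counts as upstream).
* **Driving force** (`driving_force()`): area-mean inlet gauge pressure
  times `pi r_c^2`, reported as time mean over the injection (used for
  comparisons) and peak. Whether a quoted force is a mean or a peak is
  ambiguous in parts of the literature; both are available.

## Verification and what it does and does not show

The test suite verifies, among other things:

* plane-Poiseuille (planar metric) and pipe-Poiseuille (axisymmetric
  metric) velocity profiles to within 3% at 20 cells across the conduit;
* monotone, conservative volume-fraction transport against an independent
  one-dimensional implicit-upwind oracle, and a <1% global medium budget
  over a full injection;
* the exact mirror equivalence of the half-domain with a symmetry plane
  and the full-domain solution;
* that equal phase properties make `alpha` a passive scalar (velocity
  field independent of the composition);
* the closed-form Stokes relaxation and tracer limit of the embryo
  stepper, and the equal-area initial layout;
* the qualitative regime change — upstream lobes for saline, a clean
  sector for the equal-viscosity medium — and the monotone growth of mean
  axial transport distance and driving force with medium viscosity across
  the fast-injection cases.

These checks validate the numerics and the implemented model. They do not
validate the model against a real uterus: the walls are rigid (no
peristalsis), the domain is two-dimensional, the fluids are Newtonian and
non-diffusing, embryo-wall adhesion and deformation are absent, and the
withdrawal idealizations are discussed above. Conclusions about clinical
practice are outside the package's scope.

## Known limitations

* First-order upwind diffusion at desk-scale resolution makes the lowest
  viscosity cases effectively more viscous; absolute low-viscosity
  pressures and fine vortex structure converge only under the `"fine"`
  profile.
* The stair-step mask approximates the slanted cavity wall to O(h); the
  fluid-area error is about half a percent at the bundled profiles and
  shrinks with refinement.
* The translating withdrawal under-resolves the thin lubrication layers
  around a fast-moving tip; the sliding mode ignores the shrinking
  catheter footprint. Reality sits between.
* The 15 s slow-injection scenarios are supported but expensive at the
  default time step; users should scale `dt_injection` with the injection
  time.
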