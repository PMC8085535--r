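---
title: "Models, assumptions and design choices in tkrfem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design choices in tkrfem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkrfem)
```

`tkrfem` builds total-knee-replacement (TKR) finite-element models and
studies how tibiofemoral contact pressures respond to modeling choices.
This vignette is the package's own account of the science inside it: the
constitutive models and their assumptions, the coordinate and sign
conventions, the tunable parameters with their defaults and units, what
the synthetic data emulate (and what they do not), and the numerical
choices in the reduced-order contact solver.

## Coordinate frame and units

One model frame is used everywhere: **x** mediolateral (+x medial, the
flexion-extension axis), **y** anteroposterior (+y anterior, the
varus-valgus axis), **z** vertical (+z proximal, the joint
distraction/compression axis). Gait-lab data recorded with z vertical,
x forward and y to the subject's right are converted at ingestion by the
fixed permutation `lab_to_model_frame()` (x_model = −y_lab,
y_model = x_lab, z_model = z_lab, for a right knee). Keeping a single
internal frame avoids sign errors when wiring rotations, moments and
perturbation directions together.

Units form a consistent mm–N–MPa system: lengths mm, forces N, pressures
and moduli MPa, moments N·mm, angles degrees, densities tonne/mm³.

Sign conventions for rotations are right-handed about the model axes:
internal rotation is a positive rotation about +z, varus tilt a positive
rotation about +y (it lowers the medial condyle), flexion positive about
+x. Consequently a *varus drive moment* — one that shifts load to the
medial compartment — is a **negative** y-moment: the upward contact
reaction on the medial side (+x) contributes negatively to the y-moment,
so it balances a negative applied `My`. The monotonicity property tested
in the suite (medial load share non-decreasing with varus moment) is
stated in terms of −My for this reason.

## Part roles and materials

The model has six parts. Femur, tibia, fibula and the tibial tray are
rigid bodies: bone and CoCrMo tray moduli are orders of magnitude above
the polyethylene insert's, so their deformation contributes negligibly to
insert contact mechanics while a deformable representation would multiply
solve time. The femoral component and tibial insert are deformable and
carry tetrahedral meshes.

Deformable parts use a compressible neo-Hookean material with
strain-energy density

$$\Psi = \frac{G}{2}(I_1 - 3) - G \ln J + \frac{\lambda}{2} (\ln J)^2,$$

with $I_1 = \mathrm{tr}(F^TF)$ and $J = \det F$, parameterized by
engineering constants through $E = 2G(1+v)$ and
$\lambda = 2Gv/(1-2v)$. The Cauchy stress implemented in
`cauchy_stress()`,

$$\sigma = \frac{1}{J}\left[G(B - I) + \lambda \ln J \, I\right],
\qquad B = FF^T,$$

is the unique stress consistent with this energy; the test suite verifies
the pair by central finite differences on random deformation gradients,
by frame indifference under random left rotations, and by recovery of the
isotropic linear-elastic moduli at strain $10^{-5}$. Defaults are CoCrMo
(E = 210000 MPa, v = 0.3) for the femoral component and UHMWPE
(E = 1200 MPa, v = 0.46) for the insert. Rigid parts carry a nominal
density of 7.8e-9 tonne/mm³ purely for solver-file completeness; the
quasi-static analyses never use inertia.

## Ligament model

The collaterals retained after arthroplasty (MCL, LCL) are tension-only
nonlinear springs. With strain $\epsilon = (L - L_0)/L_0$:

$$f(\epsilon) = \begin{cases}
0 & \epsilon < 0\\[2pt]
\tfrac14 k\,\epsilon^2/\epsilon_l & 0 \le \epsilon \le 2\epsilon_l\\[2pt]
k(\epsilon - \epsilon_l) & \epsilon > 2\epsilon_l
\end{cases}$$

Both branches equal $k\epsilon_l$ at $\epsilon = 2\epsilon_l$. Published
statements of this law sometimes print the quadratic branch's upper bound
as $\epsilon_l$ while describing $2\epsilon_l$ as the quadratic-to-linear
threshold; the quadratic-on-$[0, 2\epsilon_l]$ reading is the only one
that makes $f$ continuous, and is what `ligament_force_strain()`
implements.

The zero-load length — the length at which the ligament first becomes
taut — is calibrated from the reference (full-extension) pose:
$L_0 = L_r/(1+\epsilon_r)$, where $L_r$ is the attachment distance at
reference and $\epsilon_r$ the reference strain. Defaults:
MCL $k = 8250$ N, $\epsilon_r = 0.04$ (taut at extension); LCL
$k = 6000$ N, $\epsilon_r = -0.05$ (slack, so $L_0 > L_r$).

Three defaults were genuinely open and are set as follows:

- $\epsilon_l = 0.03$ (the conventional linear-limit strain for this
  spring family); configurable per bundle.
- Each bundle is a single strand (`n_strands = 1`); multi-strand bundles
  split $k$ equally so the bundle total is invariant.
- Reference-strain perturbations are *relative* scalings
  ($\epsilon_r \cdot (1 \pm p/100)$), matching the "percent from the
  reference value" formulation of the sensitivity design, and recompute
  $L_0$ holding $L_r$ fixed — the pre-tension changes, the geometry does
  not. Attachment-shift perturbations translate origin and insertion by
  the same vector, so $L_r$ and $L_0$ are preserved exactly.

## Synthetic geometry

`make_synthetic_tkr()` generates a parametric stand-in for segmented
implant geometry: two spherical condyles (radius $R_c$, default 20 mm,
centers $\pm d_{ml}/2$ with $d_{ml} = 46$ mm) joined by a bridge block;
an insert block (76 × 30 × 10 mm) whose top carries two spherical-cap
recesses (radius $R_d = 24$ mm, depth 3 mm) centered under the condyles;
a flat tray; and cylindrical bone stubs. Spherical dishes (rather than
anatomic or toroidal ones) are deliberate: the sphere-in-dish pairing
gives initial point contact and closed-form contact oracles. The
constructor rejects $R_c \ge R_d$ because conforming-edge contact would
break point-contact initialization. The fibula stub sits posteriorly on
the midline so the *surface set* stays mirror-symmetric about the
sagittal plane x = 0 — a property the tests exploit (reflection residual
below 1e-9 mm). Cell diagonals of the insert's grid triangulation flip
across x = 0 so the symmetry holds at the face level, not only for the
vertex set; condyle and stub meshes use even azimuthal counts for the
same reason. The default initial apex gap between component and insert is
2 mm.

Default attachment landmarks place the MCL at the medial condyle flank
running to the tibia and the LCL laterally to the fibula stub, giving
reference lengths around 45–60 mm. Real attachment coordinates are
subject-specific and user-supplied in any non-synthetic application.

## Mesh processing

STL files (binary or ASCII) are read as triangle soups and welded within
1e-9 mm to recover topology. `validate_surface()` reports boundary edges
(holes), non-manifold edges, duplicate vertices and degenerate faces;
a surface is watertight iff it has no boundary edges. Degenerate faces
are reported, not repaired, by default (`drop_degenerate_faces()` removes
them on request); geometry *repair* is explicitly out of scope.

`tetrahedralize()` builds volume meshes without an external mesher: each
connected component is fanned to its centroid, which is exact for
star-shaped components (spheres, boxes, cylinders — every synthetic part
except the insert). The dished insert is *not* star-shaped, so
heightfield-generated blocks carry grid metadata and are decomposed into
vertical prism columns split into three tetrahedra each. Refinement is by
longest-edge bisection until every cell is below `max_cell_volume`; new
nodes are edge midpoints, so refinement conserves total volume exactly
and keeps boundary nodes on the input surface. The bisection refines tets
independently (hanging nodes are permitted); the meshes feed solver-file
export and volume accounting, not a conforming FE assembly, and the
volume-conservation tests hold regardless. General non-star-shaped
surfaces without heightfield metadata are rejected with a clear error
rather than silently mis-meshed.

## Gait boundary conditions

`read_motion_table()` parses the OpenSim storage/motion dialect (header
keys, `endheader`, labeled columns) and enforces the declared `nRows`.
Filtering uses a zero-phase (forward-backward) Butterworth design,
default order 4 at 6 Hz cutoff for 120 Hz sampling — the conventional
gait smoothing; the forward-backward pass doubles the effective
attenuation. Odd-reflection padding absorbs the zero-initial-condition
transients so a constant series passes through unchanged.

`synth_gait()` emulates a stance-phase trial: the axial force is two
Gaussian bumps centered at 20% and 80% of stance on a constant valley
floor, scaled so the maximum equals `peak_force`; this construction has
exactly two interior maxima by design. Pattern constants (documented in
the source) modify the shape: *bouncy* sharpens the bumps (largest
|dFz/dt|), *crouch* raises the valley floor and the baseline flexion,
*smooth* widens the bumps. A small seeded jitter multiplies the bump and
floor amplitudes — amplitudes only, so it can never move or multiply the
stationary points — and makes trials reproducible: the same seed is
bitwise-identical. Flexion rises from the pattern baseline to a
mid-stance peak; the varus-valgus moment is a smooth low-amplitude curve
(a few N·m, as joint reaction analyses produce). Defaults: 0.6 s stance,
101 samples, 2000 N peak force — representative of a ~70 kg subject's
instrumented-knee recordings.

What the synthetic trials do *not* emulate: measured inter-trial
variability structure, swing phase, anteroposterior force components, and
any subject-specific coupling between flexion and load. Tests passing on
synthetic gait therefore demonstrate the pipeline's mechanics (peak
placement, determinism, equilibrium quality), not fidelity to any
subject.

`build_load_curves()` assembles the two-step protocol: step 1
(`settle_duration`, default 0.1 s) holds flexion and moment at their
initial values while the axial force ramps from zero — the femur moves
vertically until first contact, which conditions the contact state before
the gait replay in step 2. The settle duration is not stated in the
methodology this package automates; 0.1 s is a configuration default.

## Solver-file generation

`assemble_model()` enforces the structural contract: six parts with fixed
roles, rigid ties femur/femoral-component and tray/insert, sliding-elastic
contact at the articulation, three cylindrical connectors (flexion about
x driven by prescribed rotation, distraction along z driven by the axial
force, varus-valgus about y driven by the moment — exactly the drive
split of the two-step protocol), ligaments MCL femur→tibia and LCL
femur→fibula, and exactly three enabled DOFs on the femur chain
(z translation, x and y rotation); tibia, fibula and tray are fully
constrained. `write_feb()` emits FEBio-format XML (spec 3.0 default, 2.5
as a secondary dialect) with shortest-round-trip number formatting, fixed
element order and no timestamps, so writes are byte-identical —
`summarize_feb()` closes the loop by recounting every structural quantity
from the file. Ligaments serialize as discrete nonlinear springs with the
force law tabulated as force versus displacement $L - L_0$ on a fixed
strain grid ([−0.05, 0.3], 25 points): the most portable representation
across solver dialects. Contact penalties default to solver-style
defaults (auto-penalty on, no augmentation, frictionless) and are
exposed in the interface types. Step controls default to 10 increments
for the settling step and one per boundary-condition sample for the gait
step.

## Reduced-order contact solver

The full nonlinear FE contact solve is replaced, at desk scale, by a
Winkler elastic foundation: the insert's articular faces act as
independent springs, per-face pressure $p = k_f\,g^+$ with $g^+$ the
positive part of the penetration of the rigid femoral surface measured
from the face centroid along the face normal. The foundation modulus
defaults to the confined-layer formula

$$k_f = \frac{E(1-v)}{(1+v)(1-2v)\,h}$$

with the insert's UHMWPE constants and the local layer thickness $h$
measured from the mesh (centroid height above the insert bottom). This
idealization keeps the pipeline testable against closed forms: a flat
punch gives uniform $p = F_z/A$, and a rigid sphere on a flat foundation
gives $F = \pi k_f R \delta^2$; the suite holds both to 1% at several
thousand contact faces.

Per gait sample the solver finds the vertical offset $u_z$ and
varus-valgus angle $\phi$ (flexion $\theta$ is prescribed) such that the
vertical contact-plus-ligament force balances the applied $F_z$ to
1e-6 relative and the y-moment balances the applied $M_y$ to
1e-6·max(|My|, 1). Numerics:

- Penetration queries are Möller–Trumbore ray casts against the femoral
  mesh (Rcpp), accelerated by a uniform 2D grid over the mesh's xy
  bounding box with ordered cell traversal; rays are near-vertical so the
  walk touches few cells.
- The primary iteration is damped Newton on $(u_z, \phi)$ with a
  forward-difference Jacobian, clamped steps (0.5 mm, 1°) and halving
  line search, warm-started along the gait cycle.
- Newton stalls in one physically meaningful regime: when a single
  condyle carries all load, the moment is insensitive to $\phi$ until the
  second condyle engages (a singular Jacobian column). The fallback is a
  nested bracketed solve — outer Illinois iteration on $\phi$ driving the
  moment residual, which is monotone decreasing in $\phi$ for dished
  geometry, with an inner Illinois solve of the monotone vertical force
  balance per $\phi$ — used only to enter the both-condyles-engaged
  region, after which Newton performs the final polish (the inner-solve
  noise floor sits above tight absolute moment tolerances; Newton's exact
  evaluations do not).
- First contact (`settle_to_contact()`) is an Illinois iteration on the
  signed apex clearance, returning the largest downward offset whose
  maximum penetration is below tolerance. A pre-penetrating start is an
  error pointing at geometry or alignment.
- A zero-force sample short-circuits to the settled pose with an
  identically zero pressure field.
- Stance fraction is defined as $t/t_{end}$ of the supplied trial (each
  trial is treated as a stance-phase record). `peak_metrics()` picks the
  interior force maxima nearest 20% and 80% of stance; equidistant
  candidates resolve to the earlier sample, and fewer than two interior
  maxima fall back to the 20%/80% indices with a warning. Reported peak
  pressures are per-face (elemental) maxima — the nodal-vs-elemental
  choice is not standardized, and the per-face value is the natural one
  for a foundation model.

The solver deliberately omits: stress fields inside the insert,
friction, inertia, and any claim of parity with a full FE solve. Its
role is to make every downstream operation (gait runs, peak metrics,
sensitivity batches) executable and testable end to end.

## Sensitivity suite

`build_perturbation_grid("ligament_table")` reproduces the published
one-at-a-time ligament design: 5 mm attachment shifts (a joint
both-ligament row per anatomical plane plus the four single-ligament
directions), reference strain scaled ±5% and ±10%, stiffness ±10%, each
applied to MCL, LCL or both — 33 perturbed rows with the printed labels.
The alignment design holds varus/valgus tilt at 1°, 3°, 5° and
internal/external rotation at 1°, 5° — 10 rows. The rotation pivot for
malalignment defaults to the model's joint center (the femoral
bounding-box centroid when none is given); the original study does not
state its pivot, so it is configuration here.

`var_pct()` is the relative percentile variation
(estimated − reference)/reference × 100, computed at full precision;
presentation rounding is half-up to two decimals
(`round_half_up()`, with a one-part-in-10¹² nudge because binary floats
sit just below most decimal ties). Recomputing the published percentage
columns from the published pressure columns reproduces every asserted
value; the one cell where the published table disagrees with its own
running text (external rotation 5°, first peak: 67.82 printed in the
table, 67.92 in the text and by the arithmetic) is reported as the
recomputed 67.92.

`compare_force_curves()` reports RMS, mean and STD variations between a
predicted and a reference force series; STD is population-form by default
(the convention is not stated in the source methodology; a sample-form
switch is provided).

`run_sensitivity()` rebuilds each perturbed model independently (no state
leakage between rows), re-settles, runs the gait cycle, extracts peak
pressures and reports VAR against the reference row; per-row failures are
recorded in a status column without aborting the batch.

## Problem sizes and test design

The suite exercises the solver at deliberately chosen sizes: oracle
checks at 2592–5000 contact faces (where both closed forms agree within
1%), full gait runs at 101 samples on a half-resolution synthetic knee
(≈1100 contact faces), and sensitivity batches on small grids at coarse
resolution. These sizes are where the method's error bounds are already
met; scaling further up changes runtime, not conclusions. The
acceptance script (`scripts/acceptance.R`) re-derives its quantities at
these same sizes.

## Known limitations

- Absolute contact pressures of the original subject-specific study, its
  measured force curves, and the crouch-trial RMS/Mean/STD variations
  require the subject's data and a full FE solve; this package
  substitutes structural reproduction, closed-form oracle agreement and
  qualitative direction checks (e.g. 5° varus tilt raises the
  single-compartment peak pressure on the synthetic model).
- The synthetic geometry is far less conforming than a real insert, so
  its absolute pressures are high; only variations and directions are
  meaningful on it.
- The foundation model ignores shear coupling between neighboring
  springs, so pressure distributions are slightly stiffer-edged than a
  continuum solve.
- Tetrahedral refinement is non-conforming (hanging nodes); adequate for
  export and volume accounting, not for direct FE assembly.
- Cruciate ligaments (resected in the modeled arthroplasty), ligament
  wrapping, viscoelasticity, patellofemoral mechanics and muscles are out
  of scope.
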