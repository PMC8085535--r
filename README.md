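# tkrfem

Automated construction and reduced-order analysis of subject-specific
**total knee replacement (TKR) finite-element models** in R.

After a knee arthroplasty, the load path through the joint runs from the
metallic femoral component onto the polyethylene tibial insert, restrained
by the retained collateral ligaments (MCL, LCL). Where the surgeon places
the implant — a degree or two of varus/valgus tilt or internal/external
rotation — and how the ligaments are balanced changes the contact pressure
on the insert, and with it polyethylene wear and implant survival. Building
the finite-element model that quantifies this is normally a slow manual
job: segment the bones, repair and remesh the geometry, assign materials,
wire up contacts, connectors and boundary conditions, and write the solver
input file. `tkrfem` automates that pipeline and adds the sensitivity
machinery around it, so that one scripted run produces a family of models
(reference plus perturbations) and the variation of their peak contact
pressures.

The package is aimed at biomechanics researchers who want a scriptable,
testable TKR modeling pipeline: every stage is an ordinary R function with
a programmatically generated synthetic geometry available, so the whole
chain runs (and is tested) without any clinical data or external solver.

## What's inside

**Models and algorithms**

- *Ligaments.* MCL and LCL as tension-only nonlinear springs
  (Blankevoort-type). With strain ε = (L − L₀)/L₀,

      f(ε) = 0                 ε < 0
      f(ε) = ¼ k ε² / εl       0 ≤ ε ≤ 2 εl
      f(ε) = k (ε − εl)        ε > 2 εl

  continuous at ε = 2 εl. The zero-load length is calibrated from the
  reference (full extension) pose, L₀ = Lr / (1 + εr), with
  k = 8250 N, εr = 0.04 (MCL) and k = 6000 N, εr = −0.05 (LCL) as
  defaults. Perturbation operators shift both attachments rigidly
  (preserving L₀) or rescale εr / k by signed percentages.
- *Materials.* Compressible neo-Hookean implant materials,
  Ψ = G/2 (I₁ − 3) − G ln J + λ/2 (ln J)², parameterized by engineering
  constants via E = 2G(1+v), λ = 2Gv/(1−2v). Defaults: CoCrMo
  (E = 210000 MPa, v = 0.3) for the femoral component, UHMWPE
  (E = 1200 MPa, v = 0.46) for the insert; bones and tray are rigid.
- *Geometry.* Triangulated surface meshes with STL I/O, validity checks
  (holes, non-manifold edges, duplicate vertices, degenerate faces),
  tetrahedralization, rigid alignment perturbations, and a parametric
  synthetic TKR generator (two spherical condyles on a dished insert,
  mirror-symmetric, watertight).
- *Boundary conditions.* OpenSim `.sto`/`.mot` ingestion, zero-phase
  Butterworth filtering, and a parameterized stance-phase gait synthesizer
  producing the canonical two-peak axial-force curve (maxima at 20% and
  80% of stance), a flexion curve, and a varus-valgus drive moment.
- *Solver file generation.* Assembly of the six-part model (femur, tibia,
  fibula, femoral component, insert, tray) with two rigid ties, one
  sliding-elastic contact, three cylindrical joint connectors (flexion x,
  distraction z, varus-valgus y) and the two-step protocol (contact
  settling, then gait), exported as FEBio-format XML with byte-stable
  output.
- *Reduced-order contact solver.* A Winkler elastic-foundation model of
  the insert (pressure ∝ local penetration, confined-layer modulus
  k_f = E(1−v)/[(1+v)(1−2v)h]) under the rigid femoral component,
  solved quasi-statically for vertical offset and varus-valgus angle at
  each gait sample. Produces pressure fields, total contact force, center
  of pressure, and the peak-pressure metrics P1/P2 at the two axial force
  peaks.
- *Sensitivity suite.* One-at-a-time perturbation grids matching the
  published ligament (33 rows) and malalignment (10 rows) designs, the
  relative percentile variation VAR = (estimated − reference)/reference ×
  100, and RMS/Mean/STD force-curve comparison metrics.

## Worked example

```r
library(tkrfem)

# synthetic geometry, ligaments, gait
gp  <- synthetic_geom_params()           # R_c = 20, R_d = 24, d_ml = 46 mm
geo <- make_synthetic_tkr(gp)
lig <- make_default_bundles(synthetic_landmarks(gp))
bc  <- synth_gait("normal", peak_force = 2000, n_points = 101, seed = 1)

# reduced-order contact model and gait run
fnd  <- foundation_model(geo$tibial_insert)
knee <- contact_model(geo$femoral_component, fnd, lig,
                      joint_center = c(0, 0, 29))
traj <- run_gait(knee, bc)
print(traj)
#> gait_trajectory 'synthetic_normal': 101 steps, peak force 2000.7 N, peak pressure 101.511 MPa

pk <- peak_metrics(traj, bc)
round(c(P1 = pk$P1, P2 = pk$P2), 1)
#>   P1   P2
#> 94.6 96.1
```

`P1` and `P2` are the maximum per-face contact pressures (MPa) on the
insert at the first (≈20% stance, loading response) and second (≈80%
stance, pre-swing) axial-force peaks. The synthetic geometry is far less
conforming than a real insert, so its absolute pressures are high; the
pipeline's quantitative claims are about structure, variations and the
solver's closed-form oracles, not these absolute values.

Sensitivity analysis over the malalignment design:

```r
grid <- build_perturbation_grid("alignment_table")   # 10 perturbed rows
tab  <- run_sensitivity(geo$femoral_component, fnd, lig, grid, bc,
                        joint_center = c(0, 0, 29))
attr(tab, "rounded")[1:3, c("label", "P1", "VAR1", "P2", "VAR2")]
#>                     label    P1 VAR1    P2  VAR2
#> 1 Reference configuration 94.64 0.00 96.08  0.00
#> 2        Varus tilt 1 deg 99.23 4.85 95.28 -0.83
#> 3        Varus tilt 3 deg 95.73 1.15 91.68 -4.58
```

A FEBio-format solver file for the same model:

```r
model <- build_synthetic_model(gp, bc)
write_feb(model, "model.feb")
summarize_feb("model.feb")
#> feb_digest (spec 3.0): ... 6 materials, 3 contacts, 3 connectors, 2 ligaments, 2 steps, 3 curves
```

A thin command-line front end (`inst/cli/tkrfem`) exposes the same steps
as subcommands (`synth-geom`, `gait-synth`, `build-feb`, `run`,
`sensitivity`, `compare`).

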