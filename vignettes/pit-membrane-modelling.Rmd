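---
title: "Modelling pit-membrane microstructure, microflow and mechanics"
author: "pitflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pit-membrane microstructure, microflow and mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pitflow)
```

## The system

Bordered pit membranes are the porous primary-cell-wall layers through
which xylem sap passes between neighbouring conduits. In angiosperms
they are mats of cellulose microfibrils a few hundred nanometres thick,
with pore constrictions of a few to a few tens of nanometres; they set a
large share of a plant's hydraulic resistance and gate the spread of
embolism (air seeding). `pitflow` builds virtual three-dimensional
membranes, analyses their pore space, solves creeping flow through them,
and estimates their mechanical response — a chain that connects fibre
geometry to hydraulic and mechanical function.

## Microstructure generation: rigid sequential settling

`deposit_network()` drops rigid, horizontal cylindrical fibril segments
one at a time onto a flat plate. Each candidate has a uniformly random
in-plane orientation over $[0, \pi)$ and a uniformly random centre over
the tile; it falls straight down until it first touches the plate (axis
height = its radius) or an earlier fibril. Because all fibrils are
horizontal, the first-contact height against an existing fibril has a
closed form: if the in-plane closest approach of the two axes is $d_{xy}$
and the sum of radii $R$, contact occurs at a vertical offset
$\sqrt{R^2 - d_{xy}^2}$. The resting height is the maximum over all such
contacts, so the deposited stack is exactly supported and exactly
non-penetrating (both are verified per network by `validate_network()`
and property tests).

Fibrils neither bend nor settle further after first contact, and no
torque balance is applied. This keeps every contact computation exact
but has a structural consequence worth stating plainly: long rigid rods
prop each other up into an unrealistically tall, loose "log-pile". Real
microfibrils are flexible and drape over one another. We therefore use
*short rigid segments* as the deposited unit — an effective
representation of the conformable span of a long fibril between contact
points, not a claim about physical fibril length.

### Default parameters and their calibration

Two observable anchors fix the defaults once: a mean membrane thickness
of roughly 300 nm, and fresh angiosperm constriction sizes in the
5–20 nm range. With segment diameter 10 nm (within the reported range of
cellulose fibril bundles), segment length 20 nm and 3400 segments on a
500 × 500 nm tile, deposited stacks reach ≈ 300 nm thickness and a
pooled median constriction diameter of ≈ 16 nm (10 seeds, 2.5 nm
voxels). All four numbers are exposed in `deposition_params()` and can
be swept freely; the calibration was done once, against those two
anchors, and not revisited.

What the generator does *not* emulate: fibril flexibility and
post-deposition compaction of the stack, chemistry (pectin coatings,
hydrogels) that narrows effective pores, bundling/branching of fibrils,
and any lamellar ordering beyond what sequential settling produces.
Passing tests on these synthetic structures therefore validates the
numerics and the stated geometric invariants — not the full realism of
natural membranes.

## Pore structure: distance transform and watershed

`voxelize()` discretizes the network (a voxel is solid iff its centre
lies within one radius of a fibril axis; resolution guard: voxel ≤
diameter/4). `extract_pore_graph()` then computes the exact Euclidean
distance transform of the fluid phase and segments it by watershed:
pores are catchment basins of the distance map, constrictions are the
ridge saddles between adjacent basins. Basins whose peak rises less than
one voxel above the meeting saddle are merged (an h-maxima criterion
tied to the resolution), which suppresses voxel-noise
over-segmentation.

Sizes follow the maximal-ball convention: pore equivalent diameter =
2 × the distance peak of the basin; constriction diameter = 2 × the
distance value at the saddle. Distances are measured between voxel
centres with no half-voxel surface correction: solid voxel centres sit
about half a voxel behind the nominal surface, which compensates the
staircase bite of voxelized walls — on analytic fixtures (cylindrical
holes, spherical cavities, necks) both conventions were checked and the
uncorrected one stays within one voxel of truth for pores *and*
constrictions. A constriction is never wider than either adjacent pore,
by construction.

Pathway analysis treats the lateral faces as walls and the two z-faces
as inlet and outlet. `through_path_count()` counts edge-disjoint
inlet–outlet paths through a pore as the minimum of two unit-capacity
max-flows (inlet→pore and pore→outlet, computed with igraph); necks
narrower than `min_diameter` (default one voxel) are excluded.
`obstruction_index()` is 1 − (widest-path bottleneck through the pore) /
(pore equivalent diameter), clamped to [0, 1], with sealed pores
(no path) scored 1. Bottlenecks come from a max-bottleneck Dijkstra run
once from each face. For graphs with parallel independent necks between
the same pore pair, note that the saddle bookkeeping keeps one
(the widest) constriction per pore pair; path multiplicity through
*distinct* intermediate pores is counted exactly.

## Microflow: staggered-grid Stokes and Darcy upscaling

`solve_stokes()` solves the steady Stokes equations — the pressure
gradient balancing viscous stresses, with incompressibility — on a
marker-and-cell staggered grid over the voxel mask. No-slip on all
fibril surfaces enters through the stencil: velocity components normal
to a solid face vanish on that face, and tangential components see a
reflected ghost value, which places the wall exactly on the cell face
(second-order). Flow is driven either by a prescribed pressure
difference between the two z-faces (reservoir layers are padded onto
both faces) or, for periodic unit-cell problems, by a body force with
z-periodicity. Lateral boundaries are periodic by default, with
free-slip walls as an option.

The discrete saddle-point system is solved by conjugate gradients on the
pressure Schur complement (Uzawa-CG): each iteration solves the three
decoupled momentum Poisson problems with multigrid-preconditioned CG and
updates pressure and velocity incrementally, so the divergence of the
velocity field is the outer residual. The Schur complement of this
operator is spectrally equivalent to a pressure mass matrix, which makes
the outer iteration count essentially grid-independent; a diagonal
"mobility" preconditioner (summed inverse stencil diagonals of the open
faces around each cell) equalizes open regions against tight throats.
The momentum multigrid uses per-axis aggregation coarsening (odd
dimensions allowed; the last coarse cell absorbs three fine planes) with
pure Galerkin coarse operators under piecewise-constant prolongation.
After convergence a final exact projection drives the discrete
divergence to round-off, so the cross-sectional flux is identical at
every z-plane — mass conservation holds to machine precision rather
than to the iteration tolerance.

Numerical tolerances: the outer tolerance is the relative L2 Schur
residual (default `tol = 1e-8` for fixture-scale runs; membrane-scale
workflows in this package use `1e-3`–`1e-4`, which changes upscaled
permeability by well under 1%). Momentum solves use a relative inner
tolerance `mom_tol` (default `1e-4`); direction solves inside the outer
CG run three times looser, guarded by periodic recomputation of the true
residual. Solver validation: plane-slit and Hagen–Poiseuille closed
forms to ≲ 1%, transverse square cylinder arrays against the
Drummond–Tahir series (and, during development, against an independent
spectral penalization solver, which agreed with this solver to ~3% and
showed the truncated series itself reads ~12% high at solid fraction
0.3), exact linearity in the driving pressure, and exact plane-flux
constancy.

`summarize_flow()` upscales with one-dimensional Darcy's law
$k = Q \mu L / (A \Delta P)$ over the full tile area and membrane
thickness, and reports the particle Reynolds number
$\mathrm{Re} = \rho \bar v d_f / \mu$ built on the volume-averaged pore
velocity magnitude and the fibril diameter. For default membranes under
water at 20 °C (ρ = 998 kg m⁻³, μ = 10⁻³ Pa s) and a 1000 Pa drop,
Re ≈ 10⁻⁶ — firmly in the creeping-flow regime the model assumes.
`per_pore_flux()` attributes the through-flux to watershed pores
slice-by-slice, normalized by the total flow; fractions over a full
cross-section sum to one.

### What flux attribution shows on these structures

Across seeded default networks, per-pore flux fraction rank-correlates
strongly with pore size (Spearman ≈ 0.8 against the maximal-ball
diameter) and only weakly with the scale-free openness
1 − obstruction index (≈ 0.1). Every network
does contain top-quartile-diameter pores carrying below-median flux —
individual big-but-obstructed pores are real and reproducible — but as a
*population statistic* size dominates on these uniformly connected,
high-porosity synthetic stacks. Two design facts explain this: absolute
flux through a pathway scales with the absolute bottleneck width (a
size-bearing quantity), while the obstruction index is deliberately
normalized by pore size; and rigid sequential settling produces
vertically well-connected pore space with few strongly blocked large
pores. Denser or laminated mats (compacted stacks, flexible draped
fibrils) would be expected to shift the balance toward obstruction; the
generator cannot reach such structures, and we report the measured
outcome rather than tune toward a different one.

## Mechanics: Cox estimate and bonded beam network

`cox_modulus()` implements the classical shear-lag estimate for a planar
mat of long, randomly oriented fibres, $E = v_f E_f / 3$: the in-plane
stiffness is the fibril modulus scaled by volume fraction with the 1/3
orientation average. It is exact by construction and serves as the
analytic reference for the network simulation.

`build_beam_model()` converts a deposited network into a frame model:
every fibril is a chain of 3D Euler–Bernoulli beam elements with
circular cross-section, split at each fibril–fibril contact (centre-line
distance within the sum of radii plus a bond tolerance); the two contact
nodes are tied rigidly — they share all six degrees of freedom,
neglecting the small lever arm (≈ one diameter) across the bond.
Sequential settling leaves each fibril touching only what it rests on —
by itself a forest of support chains with almost no lateral load path —
whereas physical microfibrils bond wherever they lie within molecular
range. Near-contacts within `bond_tol` (default 5 % of the fibril
diameter, ≈ 0.5 nm) are therefore welded too; this is the parameter that
controls network connectivity and should be swept when bond density
matters. Grips are the node sets
within one fibril diameter of the two opposite tile edges along the
tension axis. `uniaxial_tension()` applies displacement-controlled
loading: grip translations are clamped, one grip is displaced in equal
increments, each step is a linear sparse solve (Matrix), and elements
whose axial strain exceeds the material failure strain are deleted
before the next step. With no failure criterion the response is exactly
linear; with one, the broken-element set grows monotonically and a
disconnected specimen is flagged and truncated rather than crashing. A
uniform-stretching (biaxial) variant displaces both in-plane grip pairs.
A tiny relative diagonal regularization (1e-8 of the stiffness scale)
absorbs the torsional null mode of perfectly collinear chains; its
effect on forces is orders of magnitude below the reported tolerances.

The simulated initial modulus of deposited mats runs roughly an order of
magnitude above the Cox estimate at the same volume fraction. That gap
is expected: the shear-lag formula describes long spanning fibres
loaded through matrix shear, while the welded short-segment frame
carries load through stiffer truss-like paths; and sequential rigid
settling cannot reach the volume fractions (≳ 0.2) where the two models
would be expected to approach each other. The package asserts only that
the two stay within about 1.5 orders of magnitude.

## Pipeline and reproducibility

`run_pipeline()` chains the stages per seed from a validated YAML
configuration (unknown keys are rejected; all lengths and pressures may
carry unit suffixes — the nm↔SI mix being the likeliest silent-error
source). Every stochastic stage is seeded, so a configuration determines
the report bit for bit; one failing seed is recorded in its entry and
never aborts the batch. Artifacts (fibril CSV + JSON sidecar, pore
tables, legacy-VTK fields, beam displacement exports) carry version and
configuration-hash provenance.

Problem sizes used by the shipped checks, chosen to keep a full run
lightweight while exercising every code path: solver oracles on
≤ 160 × 160 × 4…40-voxel fixtures; membrane-scale statements on the
default 500 × 500 nm tile at 5 nm voxels; the constriction-size
calibration at the full 2.5 nm resolution it was defined at.

```{r example}
net <- deposit_network(deposition_params(seed = 42))
grid <- voxelize(net, 2.5)
pg <- extract_pore_graph(grid)
field <- solve_stokes(grid, fluid_props(), dP = 1000, tol = 1e-3)
summarize_flow(field, characteristic_diameter = 10)
```

## Known limitations

- Rigid, horizontal, straight segments: no draping, no compaction, no
  out-of-plane tilt; stack porosity is consequently high (~0.9).
- Constriction statistics inherit a one-voxel uncertainty from the
  maximal-ball convention on a lattice.
- The pore graph keeps one constriction per adjacent pore pair;
  parallel necks between the same two pores are represented by the
  widest.
- Rigid contact ties ignore bond compliance and the contact lever arm;
  fracture is element deletion at a strain threshold, with no
  plasticity.
- Capillary (meniscus) effects, fibril deformation under flow, ionic
  and coating chemistry are out of scope by design.
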