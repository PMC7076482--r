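# pitflow

Virtual xylem pit membranes: microstructure generation, pore and
constriction analysis, creeping-flow simulation with Darcy upscaling,
and fibril-network mechanics — in one R package.

Bordered pit membranes are the nanoporous cellulose mats (typically
~300 nm thick, with 5–20 nm constrictions in fresh angiosperm material)
through which xylem sap flows between conduits. Their geometry controls
a large share of plant hydraulic resistance and the spread of embolism.
`pitflow` is aimed at plant hydraulics and porous-media researchers who
want to go from a fibre-scale structural hypothesis to hydraulic and
mechanical predictions:

1. **Microstructure** — random sequential deposition of rigid
   cylindrical microfibril segments onto a plate
   (`deposit_network()`): uniform random in-plane orientation and
   location, exact first-contact resting heights, optional circular
   clipping; seeded and bit-reproducible.
2. **Pore space** — voxelization, exact Euclidean distance transform,
   watershed segmentation into pores (catchment basins) and
   constrictions (ridge saddles), through-pathway counting by
   max-flow, and a per-pore obstruction index
   (`extract_pore_graph()`, `through_path_count()`,
   `obstruction_index()`).
3. **Microflow** — steady Stokes flow (∇p = μ∇²V, ∇·V = 0, no-slip on
   fibril surfaces) on a staggered voxel grid, solved by Schur-
   complement conjugate gradients with multigrid-preconditioned
   momentum solves; Darcy upscaling k = QμL/(AΔP), hydraulic
   conductivity, particle Reynolds number, and per-pore flux
   attribution (`solve_stokes()`, `summarize_flow()`,
   `per_pore_flux()`).
4. **Mechanics** — the Cox shear-lag estimate E = v_f·E_f/3
   (`cox_modulus()`) and displacement-controlled tension of the bonded
   fibril network as a 3D beam frame with strain-threshold fracture
   (`build_beam_model()`, `uniaxial_tension()`).
5. **Pipeline** — a YAML-configured end-to-end driver with strict
   validation, per-seed crash isolation and full provenance
   (`run_pipeline()`), plus CSV/JSON/legacy-VTK exporters and a thin
   command-line driver in `inst/cli/pitflow.R`.

## Worked example

```r
library(pitflow)

net  <- deposit_network(deposition_params(seed = 42))
net
#> <fibril_network> 3400 fibrils, tile 500 x 500 nm, thickness 290.2 nm, seed 42

grid <- voxelize(net, 2.5)          # 2.5 nm voxels
pg   <- extract_pore_graph(grid)
pg
#> <pore_graph> 524 pores, 2066 constrictions, median constriction 15.8 nm

field <- solve_stokes(grid, fluid_props(density = 998, viscosity = 1e-3),
                      dP = 1000, tol = 1e-3)   # water at 20 C, 1000 Pa drop
summarize_flow(field, characteristic_diameter = 10)
#> <flow_summary> Q = 3.811e-17 m^3/s, k = 4.459e-17 m^2, Re = 1.83e-06,
#>                flux spread 8.1e-16
```

The summary says: this seed-42 membrane passes Q ≈ 3.8 × 10⁻¹⁷ m³/s of
water under a 1000 Pa drop, equivalent to a Darcy permeability of
~4.5 × 10⁻¹⁷ m², at a particle Reynolds number of ~2 × 10⁻⁶ — deep in
the creeping-flow regime, as the Stokes model assumes. The flux spread
(relative plane-to-plane variation of the cross-sectional flow rate) is
at machine precision because discrete continuity is enforced exactly.

Per-pore attribution and obstruction:

```r
flux <- per_pore_flux(field, pg)
obr  <- obstruction_report(pg)
ord  <- order(-obr$diameter_nm)
head(cbind(obr[ord, c("diameter_nm", "obstruction_index", "bottleneck_nm")],
           flux_frac = round(flux[ord], 4)), 5)
#>   diameter_nm obstruction_index bottleneck_nm flux_frac
#> 1       205.8             0.830            35    0.0585
#> 2       204.0             0.828            35    0.1044
#> 3       203.8             0.828            35    0.0936
#> 4       197.3             0.823            35    0.0165
#> 5       192.2             0.818            35    0.0986
```

The largest pores (the wide spaces where the rough membrane surface
meets the faces) all funnel their flow through ~35 nm bottlenecks, and
their flux fractions vary sixfold at essentially equal size — pore size
alone does not determine what a pore carries.

The methods vignette
(`vignettes/pit-membrane-modelling.Rmd`) documents the model
assumptions, parameter calibration, numerical choices and limitations.

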