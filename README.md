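# mrebdyn

Mechanics and curvature-guided translocation of membrane-bound protein
filaments, for cellular biophysicists studying how short, intrinsically
curved filaments such as the bacterial actin homolog **MreB** localize on
membranes of different shapes.

The package implements two coupled models:

1. **Binding mechanics.** A filament is a curved linear-elastic rod of
   bending rigidity B = πYr⁴f/4 and intrinsic curvature κₛ that binds flat
   along a membrane. Its elastic cost is

       E_bend = (πYr⁴f/8) ∫ (κ − κₛ)² dℓ,

   while the membrane carries the Helfrich energy
   ℱ = ∫ [k_b/2 (2H − H_s)² + k_t/2 K + γ] dA − p∫dV. In the Monge gauge the
   membrane deformation solves the biharmonic shape equation Δ²h = p/k_b,
   which is split into two Poisson problems (m = Δh first, then h) with
   Dirichlet data and solved by P1 finite elements. Minimizing the total
   over the filament's deformed curvature gives the binding free energy
   ΔG(θ) versus binding angle θ, the preferred orientation θ*, and a phase
   label (filament bends / membrane bends / both).

2. **Translocation dynamics.** A bound filament is a point on a parametric
   surface r(u, v) that moves processively along the direction of largest
   principal curvature, with a Gaussian angular deviation η ~ N(0, σ²) per
   step (σ = α/Δc by default, α = 0.6 rad µm⁻¹, Δc the local difference of
   principal curvatures) and a fixed on-surface step size L = 200 nm:

       X_{n+1} = X_n + χ_n ℓ_n (cos θ_n, sin θ_n),

   with ℓ_n solving the arclength equation for L. Filaments activate at
   rate k per unit membrane area, deactivate at rate λ (processivity 1/λ
   steps), and at umbilic points step in uniformly random directions. The
   steady-state concentration C_F = N_F/dA is computed both by Langevin
   simulation and by a finite-volume Fokker–Planck (Kramers–Moyal) solve,
   and summarized as region enrichment ratios, curvature–enrichment curves,
   bulge occupancies and per-hoop axial displacement statistics.

Supported geometries: plane, cylinder, spherocylinder, torus / bent rod,
helix tube, ellipsoid, bulged cylinder, undulating cylinder, non-circular
(elliptical) cylinder.

## Worked example

Steady-state localization in a donut-shaped cell (torus, tube radius
0.5 µm, centerline radius 5 µm), in the high-processivity regime:

```r
library(mrebdyn)

tor <- make_surface("torus", tube_radius = 0.5, centerline_radius = 5)
tp  <- translocation_params(lambda = 5e-4)   # mean lifetime 2000 steps

en <- simulate_ensemble(tor, tp, n_filaments = 120, max_steps = 4000,
                        n_u = 16, n_v = 48, seed = 3001)
fp <- solve_steady_state(tor, tp, n_u = 16, n_v = 48)

part <- region_partition(tor, en$field$grid)
region_enrichment(en$field, part, "inner", "midline")
#> [1] 1.097997
region_enrichment(fp, part, "inner", "midline")
#> [1] 1.100221
```

Both routes put ~1.10-fold more filaments per unit area on the inner edge
of the torus than on its midlines: with long-lived filaments the filament
*number* becomes uniform along each circumferential hoop, and the shorter
inner arclength concentrates them, close to the analytic hoop-uniform value
R_t/(R_t − r) = 10/9 ≈ 1.11. The same machinery reproduces the ~2-fold
bulk-over-pole enrichment on a spherocylinder and the enrichment of
negative-Gaussian-curvature necks on an undulating cylinder.

The binding side:

```r
sc <- binding_scan(filament_properties(), membrane_properties(), Rcell = 0.5)
sc
#> Filament-membrane binding scan (Rcell = 0.5 um)
#>   preferred angle theta* = 1.571 rad (90.0 deg)
#>   well depth deltaG(0) - deltaG(theta*) = 113.82 kBT (robust to thermal fluctuations)
#>   binding phase: filament_bends
```

A filament more curved than the cell binds circumferentially (θ* = π/2),
with an orientation well far deeper than thermal fluctuations, robustly
across turgor pressures.

A YAML-configured pipeline (`run_config()` / `run()`) and a thin CLI
(`inst/cli/mrebdyn`) wrap these stages and write CSV tables, VTK surface
fields and a JSON summary.

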