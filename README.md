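# rigidbd

Rigid-body Brownian dynamics (BD) for membrane protein association, with the
trajectory analyses that turn BD ensembles into complexes: grid-map force
fields, Boltzmann-inverted membrane restraints, pose clustering and
interaction-energy scoring, phosphomimetic rescoring, ion-crossing currents,
and HOLE-style pore radius profiles.

## Who this is for

Computational biophysicists studying how a membrane-anchored protein finds
its binding site on a membrane-embedded channel — the prototypical case being
a kinase whose N-terminal hydrophobic helix (an "anchor") inserts into the
outer mitochondrial membrane and then diffuses laterally until it docks onto
a β-barrel channel such as VDAC1. All-atom MD cannot reach the millisecond
association timescale; rigid-body BD with precomputed potential maps can,
and this package implements that protocol end to end together with synthetic
generators so every stage is testable without external data.

## The model

**Force field.** The stationary body is represented by scalar potential maps
on a regular grid (default 1 Å): one electrostatic map (imported from a
Poisson–Boltzmann solver via OpenDX, or a built-in Debye–Hückel fallback
`V(r) = 332.0636 Σᵢ qᵢ e^{−r/λ_D}/(ε_s r)`, λ_D = 3.04/√I Å) and one
Lennard-Jones map per collapsed atom category. LJ parameters are clustered
into three categories — {H}, {O,N}, {C,S} — each carrying the mean Rmin and
the mean well depth scaled by 0.3 to avoid artificial stickiness. The mobile
body becomes matching density grids (charge and per-category particle
counts, cloud-in-cell deposition). Force and torque are

F = Σ_cells ρ(cell)·(−∇V)(x_cell),  τ = Σ_cells (x_cell − COM) × f_cell,

with the gradient taken analytically from the trilinear interpolant, so the
force is the exact negative gradient of the interpolated energy. A 34 Å
cutoff is applied at map construction.

**Membrane.** No explicit membrane: the bodies' membrane midplanes are
aligned, each anchor residue's COM is coupled to a 1-D grid potential
`U(z) = −k_B T log p(z)` obtained by Boltzmann inversion of its observed
z distribution, and a flat-bottomed circular wall (default radius 150 Å)
confines lateral diffusion.

**Propagation.** Overdamped Ermak–McCammon updates at 310 K:
`Δx = (D/k_BT)F Δt + √(2DΔt)ξ`, with the rotation vector applied as an
exponential-map quaternion increment (default timestep 200 fs, output every
0.2 ns). Isotropic D from user input or a Stokes–Einstein fallback.

**Analysis.** Contacts at 3 Å minimum inter-atom distance; greedy
quality-threshold clustering on mobile-body RMSD (10 Å cutoff, no refitting —
the stationary body defines the superposition); representative = most
favourable interaction energy (Coulomb + LJ, hard 12 Å cutoff); anchor-COM
hot-spot densities (Gaussian KDE, integral 1); per-cluster electrostatic
rescoring under site charge modification (e.g. serine → phosphoserine);
ion-crossing counting by a below/inside/above state machine with
`I = N·q/τ`; pore radius as the largest clash-free probe per axial slice.

## Worked example

A charged patch on a toy barrel's membrane-level rim, a membrane-anchored
probe with a +1e head, five BD replicas of 10 ns:

```r
library(rigidbd)

cfg <- list(
  seed = 5,
  stationary = list(kind = "toy_barrel", radius = 15, height = 35,
                    rim_frac = 0.5, site_charge = -0.5, site_angle_deg = 0),
  mobile     = list(kind = "anchor_probe", n_atoms = 20, head_charge = 1),
  maps       = list(spacing = 1, cutoff = 34, solvent_dielectric = 4),
  restraints = list(temperature = 310, k = 1.0, wall_radius = 60),
  bd         = list(timestep_fs = 200, duration_ns = 10, output_stride_ns = 0.2,
                    n_replicas = 5, start_radius = 30, stokes_radius = 12),
  rescore    = list(site_resid = 999, modified_charges = c(CB = -0.1)))

res <- run_pipeline(cfg)
tidy(res$clusters)
#> # A tibble: 6 × 6
#>   cluster     n population representative rep_elec rep_vdw
#>     <int> <int>      <dbl>          <int>    <dbl>   <dbl>
#> 1       1   118    0.874               79   -162.   -0.373
#> 2       2     8    0.0593             121   -144.   -0.291
#> 3       3     4    0.0296             211    -72.2  -0.291
#> 4       4     3    0.0222             161      0    -0.424
#> 5       5     1    0.00741            107      0    -0.218
#> 6       6     1    0.00741            172      0    -0.123
```

87% of in-contact frames fall in one cluster whose representative pose has a
−162 kcal/mol electrostatic interaction energy — the replicas found the
charged patch. The anchor hot spot sits at the patch azimuth:

```r
glance(res$hotspot)
#> # A tibble: 1 × 5
#>   peak_x peak_y integral bandwidth_x bandwidth_y
#>    <dbl>  <dbl>    <dbl>       <dbl>       <dbl>
#> 1   21.9   1.57        1        4.50        4.35
```

Weakening the site's charge from −0.5e to −0.1e per atom (a charge
perturbation applied in place, the same mechanism as placing a
phosphoserine) reduces the electrostatic attraction five-fold in the
site-proximal clusters and not at all elsewhere:

```r
res$rescoring
#> # A tibble: 6 × 4
#>   cluster elec_original elec_modified ratio
#>     <int>         <dbl>         <dbl> <dbl>
#> 1       1        -126.         -25.1      5
#> 2       2        -101.         -20.2      5
#> 3       3         -43.5         -8.70     5
#> 4       4           0            0        1
#> 5       5           0            0        1
#> 6       6           0            0        1
```

`autoplot()` works on hot-spot densities, pore profiles, restraint
potentials, cumulative crossing curves and trajectories; `tidy()`/`glance()`
on clusters, currents, densities and profiles.

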