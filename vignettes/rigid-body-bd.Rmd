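---
title: "Rigid-body Brownian dynamics of membrane protein association: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body Brownian dynamics of membrane protein association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidbd)
```

# The problem and the model

Association of a membrane-anchored protein with a membrane-embedded channel
happens on timescales (microseconds to milliseconds of lateral diffusion,
many independent encounter events) that all-atom simulation cannot sample.
`rigidbd` implements the standard coarse-grained answer: treat both proteins
as rigid bodies, replace the stationary body by precomputed potential maps,
replace the mobile body by density grids, replace the membrane by
statistical restraints, and propagate the mobile body with overdamped
Brownian dynamics. The package also implements the downstream analyses that
make such simulations scientifically useful — contact detection, pose
clustering, interaction-energy scoring and charge-perturbation rescoring for
the association problem; crossing counting, ionic currents and pore-radius
profiling for the channel-permeation problem.

Three assumptions define the model's scope:

* **Rigidity.** Neither body relaxes internally; binding-induced
  conformational change is outside the model and must be examined by
  follow-up atomistic simulation of the predicted complexes.
* **Implicit solvent and membrane.** Electrostatics is a continuum field
  (imported Poisson–Boltzmann map or uniform-dielectric Debye–Hückel
  fallback); the membrane acts only through per-residue anchoring potentials
  along z and the alignment of the two bodies' membrane midplanes.
* **Overdamped dynamics.** At protein-scale friction a 200 fs timestep is
  far longer than the momentum relaxation time, so the inertialess
  Ermak–McCammon propagator is used even though the underlying physical
  picture is a Langevin equation; at this timestep the two are statistically
  indistinguishable, and the overdamped form is exactly testable against
  Boltzmann statistics.

# The force field

The stationary body's electrostatic potential is, by preference, an imported
OpenDX grid from a Poisson–Boltzmann solver (the package does not
reimplement PB; the map's provenance is recorded on the object and in run
headers). The built-in fallback is a screened-Coulomb map,

$$V(\mathbf r) = 332.0636 \sum_i \frac{q_i\,e^{-|\mathbf r-\mathbf r_i|/\lambda_D}}
{\varepsilon_s\,|\mathbf r-\mathbf r_i|},\qquad
\lambda_D = 3.04/\sqrt{I}\ \text{Å} ,$$

with 332.0636 kcal·Å/(mol·e²) the Coulomb constant in simulation units and
the 298 K water value of the Debye constant (the temperature correction to
310 K is well under the fidelity of a uniform-dielectric model). Nodes
within 1 Å of an atom centre are clamped.

Lennard-Jones interactions are collapsed into three atom categories —
hydrogens, oxygens + nitrogens, carbons + sulfurs — each carrying the
arithmetic mean of its members' Rmin and mean well depth scaled by 0.3; the
scaling compensates for the overcounting of attractive dispersion that makes
rigid coarse models artificially sticky. Each category becomes a single
spherical probe whose potential map is the direct pairwise LJ energy
(Lorentz–Berthelot combination) against every stationary atom. This reduces
the orientational averaging of an implicit-ligand-sampling map to plain
energy summation, which is exact for a one-sphere probe.

The mobile body is deposited once, in its body frame, as cloud-in-cell
(trilinear) densities: a charge grid paired with the electrostatic map and
one count grid per category paired with its LJ map. Cloud-in-cell was chosen
because it conserves deposited totals to machine precision (tested to
1e-12) and is the adjoint of the trilinear interpolation used for forces,
so grid energies converge to the pairwise sum at second order in the
spacing (verified down to 0.25 Å in the test suite).

**Numerical contracts.** The gradient is the exact analytic derivative of
the trilinear interpolant, so `grid_force_torque()` is the exact negative
gradient of the interpolated energy (finite-difference tested at 1e-4
relative); maps are clamped (default 30 kcal/mol) and finite everywhere; LJ
map contributions beyond 4 R~ij~ (pair energies below ~1e-4 kcal/mol) are
truncated for speed; out-of-bounds policy is declared per grid (`zero`,
`clamp`, `error`) and the force field uses `zero`, consistent with the 34 Å
construction cutoff.

# Membrane restraints

Anchoring potentials come from Boltzmann inversion of observed z samples of
each anchor residue: a histogram (default bin 0.5 Å) with one pseudocount in
empty interior bins, $U = -k_BT\log\hat p$, shifted to min 0. The histogram
(rather than a kernel estimate) keeps the estimator deterministic and
exactly consistent with the grid-potential coupling used at run time. Beyond
the sampled support the potential continues with the edge bin's linear
slope — a finite restoring ramp rather than an infinite wall, so a rare
excursion produces a finite force and the propagator remains stable. The
restraint force acts on each anchor residue's COM along z; its lever arm
about the body COM contributes torque like any other grid force. Lateral
confinement is a flat-bottomed harmonic wall (default radius 150 Å,
stiffness 10 kcal/mol/Å²; the stiffness is a package default, chosen so the
wall returns an excursion within a few Å without destabilising the
timestep).

Sampling the inverted potential with the package's own 1-D propagator and
re-inverting recovers the input potential to better than 0.02 kcal/mol over
the central 90% of support at the test's problem size (4×10⁶ steps), an
end-to-end closure of the restraint machinery.

# Propagation

Per step: $\Delta\mathbf x = (D/k_BT)\mathbf F\,\Delta t + \sqrt{2D\Delta t}\,\boldsymbol\xi$,
and a rotation vector $\Delta\boldsymbol\varphi = (D_{rot}/k_BT)\boldsymbol\tau\,\Delta t
+ \sqrt{2D_{rot}\Delta t}\,\boldsymbol\xi_{rot}$ applied as an exponential-map
quaternion increment with renormalisation every step. Diffusion is isotropic
(scalar $D$, $D_{rot}$): anisotropy of a compact protein changes transport
prefactors, not the stationary distribution, and pose discovery is an
equilibrium question. A Stokes–Einstein helper converts a hydrodynamic
radius to both coefficients when bead-model values are not supplied. All
randomness flows through R's RNG, so a seed makes entire replica sets
bit-reproducible (tested). A step that moves farther than two grid cells
triggers a diagnostic warning (timestep too large for the field).

The propagator's statistical mechanics is tested directly: free-diffusion
MSD against $6Dt$ (1000 replicas × 1 ns), harmonic-well variance against
$k_BT/k$ plus a Kolmogorov–Smirnov test of the full Boltzmann marginal
(10⁶ steps), and rotational decorrelation against $e^{-2D_{rot}t}$
(1000 replicas), each within 10%.

# Pose analysis

* **Contacts**: minimum inter-body atom distance ≤ 3 Å, computed with a
  spatial hash whose results are tested equal to the brute-force double loop.
* **Clustering**: greedy quality-threshold clustering on pose RMSD of the
  mobile body's reference atoms, expressed in the stationary frame with no
  refitting, 10 Å cutoff. The seed of each cluster is the frame with the
  most neighbours (earliest index on ties), which makes the procedure
  deterministic and order-stable for well-separated clusters (permutation
  tested). The RMSD matrix uses the rigid-body moment identity, so the cost
  is independent of the number of reference atoms once the 3×3 moments are
  accumulated.
* **Scoring**: pairwise Coulomb + LJ with a hard 12 Å cutoff and no
  switching function — scores rank poses; absolute energies at a hard cutoff
  carry no meaning beyond the ranking. "Most favourable" representative =
  lowest electrostatic + vdW sum.
* **Hot spots**: Gaussian KDE of the anchor-selection COM over (x, y) on a
  1 Å grid, Scott's-rule bandwidth floored at 0.5 Å (the floor keeps a
  degenerate, zero-spread frame set well-defined), renormalised to integrate
  to exactly 1.
* **Rescoring**: per-cluster mean electrostatic energy recomputed with one
  residue's atoms carrying modified charges (a phosphoserine stand-in);
  reported as ratio original/modified, defined as exactly 1 when the
  modification changes nothing (including the 0/0 case of a site outside
  the cutoff).

# Channel analyses

* **Crossings**: per-ion state machine over below/inside/above; only
  below→inside→above counts up (and the mirror down). Implementation
  compresses the side sequence and counts side-to-side transitions, which is
  identical to the state machine on sampled data and assigns a crossing to a
  sampling gap that jumps both faces in one frame (the ion did move all the
  way across). No hysteresis buffer: the slab faces are the only
  thresholds, which is what makes generator ground truth exactly
  reproducible. Lateral gating is not applied by the counter; geometric
  blocking lives in the track generator.
* **Current**: $I = Nq/\tau$ with signed elementary charges and net counts
  signed by direction; cumulative event series retained for plotting.
* **Pore profile**: at each z, the largest probe radius
  $r(c)=\min_i(|c-x_i|-\mathrm{vdw}_i)$ maximised over the slice plane by a
  0.5 Å grid search seeded from the previous slice, then Nelder–Mead
  refinement; clamped at 15 Å where the pore opens to bulk, with a flag.
  The deterministic search replaces stochastic (Monte-Carlo) probe
  placement so profiles are exactly reproducible; rotation invariance is
  tested to 0.05 Å.
* **Hydrogen bonds**: D–A < 3 Å and D–H–A angle (at H) > 120°.

# Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline needs, with machine-readable
ground truth:

* `make_toy_barrel()` — a cylindrical lattice with a charged ring and a
  named mutable "site" arc (default R = 15 Å, height 35 Å), standing in for
  a charged β-barrel rim. `rim_frac = 0.5` places the charged ring at the
  membrane midplane so that a midplane-anchored probe can only reach it from
  outside the wall.
* `make_anchor_probe()` — a 20-atom helix with four labelled anchor residues
  and an optionally charged head, standing in for an anchor helix plus
  charged tip.
* `sample_anchored_z()` — Gaussian z samples of variance $k_BT/k$, the
  statistical shape of a harmonically tethered residue, as inversion input.
* `make_ion_tracks()` — piecewise-linear tracks realising scheduled complete
  crossings plus feints; physical tracks alternate directions, so per-ion
  schedules obey $|N_{up}-N_{down}|\le 1$ (an unbalanced request is
  rejected). Noise is small against the 10 Å margins and provably cannot
  change counts.
* `make_biased_walk_tracks()` — drift–diffusion ions in a cylinder whose
  upper face passes only within a mouth radius; a completed pass recycles
  the ion to the entry side, so the up-crossing total measures flux.
* `make_cylinder_pore()` — atoms covering a cylinder (true free radius
  R − r~vdw~ everywhere) with an optional annular mouth cap; `cap_fraction`
  interpolates continuously from open to sealed.

Toy-body LJ radii default to Rmin/2 = 1.2 Å so that the LJ contact distance
(2.4 Å between atom centres) lies just inside the 3 Å contact criterion used
by the analysis — with larger radii a bound pose "touches" only transiently
and contact statistics measure the choice of radii rather than binding.

Passing tests on these fixtures demonstrates that the machinery is correct:
forces match pairwise sums, the propagator samples the right ensemble,
counters and profilers are exact on known truth, and an attractive patch is
found and identified by clustering. They do not demonstrate that a
particular real complex is predicted correctly — real systems add
force-field error, PB map quality, flexibility, and membrane chemistry that
no synthetic fixture represents.

# Verification problem sizes

The test suite and `scripts/acceptance.R` run, per invocation: 25 random
poses × three map spacings (1, 0.5, 0.25 Å) for force fidelity on 20-atom
bodies; 1000 replicas for the diffusion statistics; 10⁶ inversion samples
and 4×10⁶ sampler steps for the round trip; 100 scheduled track sets for
counting; and 20 association replicas × 60 ns (3×10⁵ steps each) plus a
12-replica run with the patch moved to 120° for binding-site recovery. The
force-fidelity fixture carries net charges (+4e/−3e): a near-neutral random
blob has a cancelling net force at 15–20 Å separation, and the relative
error of a cancelling sum is ill-conditioned — the monopole-carrying fixture
matches the charged-protein regime the method targets. Association success
is assessed over each replica's final 2 ns rather than its single final
frame, because a bound pose breathes thermally in and out of the 3 Å
criterion (tail contact fractions of 40–60%); a single-frame check would
measure that breathing, not binding.

# Known limitations

* The Debye–Hückel fallback has no low-dielectric protein interior or
  membrane slab; quantitative electrostatics near the surface needs an
  imported PB map.
* One mobile body per run; no hydrodynamic interactions between bodies.
* The LJ category reduction and 0.3 well-depth scaling are a recognised
  coarse approximation: they preserve excluded volume and rough contact
  energetics, not packing detail.
* Clustering is deterministic greedy quality-threshold; for clusters that
  are not well separated relative to the cutoff, memberships near the
  boundary depend on seed-frame choice (the tie-break is documented and
  index-stable).
* The crossing counter is purely z-threshold based; an ion passing outside
  the channel lumen (if the geometry allows it) would be counted. Pair the
  counter with laterally gated tracks, or confine ions, when that matters.
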