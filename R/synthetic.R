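# Synthetic fixtures emulating the statistical structure of the pipeline's
# inputs: a charged beta-barrel-like stationary body, a mobile anchored
# probe, anchored z samples, scheduled ion tracks with known crossing
# counts, biased-walk tracks through a (partially occluded) pore, and
# atom-built cylinders of known radius. Every generator is a pure function
# of its parameters and seed; ground truth travels as attributes.

#' Toy charged barrel (stationary body)
#'
#' Atoms on a cylindrical lattice emulating a beta-barrel channel: a
#' designated rim ring carries a charge pattern, and a contiguous arc of rim
#' atoms forms a named, mutable "site" residue (`resid = site_resid`,
#' resname `"SIT"`) for charge-perturbation tests. The barrel axis is z and
#' the barrel is centred at the origin with its rim at `height/2`.
#'
#' @param radius Barrel radius (Angstrom), default 15.
#' @param height Barrel height (Angstrom), default 35.
#' @param n_per_ring Atoms per ring (default 24; at least 3).
#' @param ring_spacing Vertical ring spacing (default 2.5 Angstrom).
#' @param rim_frac Height fraction (0 bottom, 1 top) of the charged "rim"
#'   ring carrying the charge pattern and the site arc; 0.5 places it at the
#'   membrane midplane so a midplane-anchored probe can only dock from
#'   outside the wall.
#' @param rim_charge Charge (e) on each non-site rim atom.
#' @param site_charge Charge (e) on each site-arc rim atom.
#' @param site_angle_deg Azimuth of the site arc centre (degrees).
#' @param site_halfwidth_deg Half-width of the site arc (degrees).
#' @param site_resid Residue id assigned to the site atoms (default 999).
#' @param jitter Gaussian positional jitter sd (Angstrom), default 0.
#' @param seed RNG seed (only used when `jitter > 0`).
#' @return A [bd_structure()]; `attr(, "site_resid")` names the mutable
#'   residue.
#' @export
make_toy_barrel <- function(radius = 15, height = 35, n_per_ring = 24,
                            ring_spacing = 2.5, rim_frac = 1, rim_charge = 0,
                            site_charge = 0, site_angle_deg = 0,
                            site_halfwidth_deg = 30, site_resid = 999L,
                            jitter = 0, seed = 1L) {
  if (radius <= 0 || height <= 0) abort("radius and height must be positive")
  if (n_per_ring < 3) abort("n_per_ring too small to close the cylinder (need >= 3)")
  set.seed(seed)
  n_rings <- floor(height / ring_spacing) + 1
  ang <- seq(0, 2 * pi, length.out = n_per_ring + 1)[-(n_per_ring + 1)]
  grid <- expand.grid(a = ang, ring = seq_len(n_rings))
  z <- -height / 2 + (grid$ring - 1) * ring_spacing
  rim_ring <- max(1, min(n_rings, 1 + round(rim_frac * (n_rings - 1))))
  rim <- grid$ring == rim_ring
  dang <- abs(((grid$a * 180 / pi - site_angle_deg + 180) %% 360) - 180)
  site <- rim & dang <= site_halfwidth_deg
  n <- nrow(grid)
  atoms <- tibble(
    serial = seq_len(n), name = "CB", element = "C",
    resname = ifelse(site, "SIT", "BAR"),
    resid = ifelse(site, site_resid, seq_len(n)),
    chain = "A",
    x = radius * cos(grid$a), y = radius * sin(grid$a), z = z,
    charge = ifelse(site, site_charge, ifelse(rim, rim_charge, 0)),
    lj_rmin_half = 1.2, lj_epsilon = 0.1, vdw_radius = 1.5)
  if (jitter > 0) {
    atoms$x <- atoms$x + rnorm(n, 0, jitter)
    atoms$y <- atoms$y + rnorm(n, 0, jitter)
    atoms$z <- atoms$z + rnorm(n, 0, jitter)
  }
  out <- bd_structure(atoms, title = "toy barrel")
  attr(out, "site_resid") <- site_resid
  out
}

#' Toy anchored probe (mobile body)
#'
#' A short helical body emulating a membrane-anchoring N-terminal helix:
#' `n_atoms` atoms on a helix of the given pitch along z, with four labelled
#' anchor residues (`M1`, `F10`, `N15`, `Q20` scaled to the chain length)
#' serving as restraint handles, and an optional charged head.
#'
#' @param n_atoms Number of atoms (default 20).
#' @param pitch Axial rise per atom (default 1.5 Angstrom).
#' @param helix_radius Helix radius (default 2.3 Angstrom).
#' @param head_charge Charge (e) placed on the first atom (default 0).
#' @param jitter Gaussian positional jitter sd, default 0.
#' @param seed RNG seed (used when `jitter > 0`).
#' @return A [bd_structure()]; `attr(, "anchors")` is a tibble with columns
#'   `label` and `resid` naming the four anchor residues.
#' @export
make_anchor_probe <- function(n_atoms = 20, pitch = 1.5, helix_radius = 2.3,
                              head_charge = 0, jitter = 0, seed = 1L) {
  if (n_atoms < 4) abort("an anchored probe needs at least 4 atoms")
  set.seed(seed)
  i <- seq_len(n_atoms)
  theta <- (i - 1) * 100 * pi / 180   # ~alpha-helical twist
  anchor_ids <- unique(pmin(n_atoms, ceiling(c(1, 10, 15, 20) / 20 * n_atoms)))
  while (length(anchor_ids) < 4) anchor_ids <- unique(c(anchor_ids, n_atoms))
  atoms <- tibble(
    serial = i, name = "CA", element = "C", resname = "ANC", resid = i,
    chain = "M",
    x = helix_radius * cos(theta), y = helix_radius * sin(theta),
    z = (i - 1) * pitch,
    charge = ifelse(i == 1, head_charge, 0),
    lj_rmin_half = 1.2, lj_epsilon = 0.1, vdw_radius = 1.5)
  if (jitter > 0) {
    atoms$x <- atoms$x + rnorm(n_atoms, 0, jitter)
    atoms$y <- atoms$y + rnorm(n_atoms, 0, jitter)
    atoms$z <- atoms$z + rnorm(n_atoms, 0, jitter)
  }
  out <- bd_structure(atoms, title = "anchored probe")
  attr(out, "anchors") <- tibble(label = c("M1", "F10", "N15", "Q20"),
                                 resid = anchor_ids[1:4])
  out
}

#' Gaussian z samples of a harmonically anchored residue
#'
#' Equilibrium samples of a coordinate in a harmonic well of force constant
#' `k`: variance `k_B T / k`. Stands in for the per-residue z distributions
#' observed in membrane-bound simulations, as input to [boltzmann_invert()].
#'
#' @param k Force constant, kcal/mol/A^2.
#' @param z0 Well centre (Angstrom).
#' @param n Number of samples.
#' @param temperature Temperature in Kelvin.
#' @param seed RNG seed.
#' @return Numeric vector of z samples.
#' @export
sample_anchored_z <- function(k, z0 = 0, n = 1e5, temperature = 310,
                              seed = 1L) {
  if (k <= 0) abort("force constant must be positive")
  set.seed(seed)
  rnorm(n, z0, sqrt(kT(temperature) / k))
}

#' Scheduled ion tracks with known crossing counts
#'
#' Piecewise-linear z tracks realising, exactly, a scheduled number of
#' complete up/down crossings per ion plus scheduled feints (excursions into
#' the slab that return to the same side). Crossings alternate physically,
#' so per ion `|n_up - n_down| <= 1`; ions with `n_down > n_up` start above
#' the slab. Optional Gaussian noise is small relative to the 10 Angstrom
#' margin and cannot change the counts.
#'
#' @param schedule Tibble with columns `species`, `n_up`, `n_down`,
#'   `n_feints` (one row per ion).
#' @param slab Membrane bounds (default `c(-20, 20)`).
#' @param dt_ns Sample spacing (default 0.5 ns).
#' @param samples_per_leg Samples per waypoint leg (default 4).
#' @param noise Gaussian noise sd on z (Angstrom), default 0.
#' @param seed RNG seed.
#' @return An [ion_tracks()] table; `attr(, "truth")` stores the schedule.
#' @export
make_ion_tracks <- function(schedule, slab = c(-20, 20), dt_ns = 0.5,
                            samples_per_leg = 4, noise = 0, seed = 1L) {
  set.seed(seed)
  margin <- 10
  below <- slab[1] - margin; above <- slab[2] + margin
  mid <- mean(slab)
  rows <- lapply(seq_len(nrow(schedule)), function(i) {
    nu <- schedule$n_up[i]; nd <- schedule$n_down[i]
    nf <- if (!"n_feints" %in% names(schedule)) 0 else schedule$n_feints[i]
    if (abs(nu - nd) > 1)
      abort("single-ion schedules must alternate: |n_up - n_down| <= 1")
    start_below <- nu >= nd
    side <- if (start_below) below else above
    wp <- side
    for (f in seq_len(nf)) wp <- c(wp, mid, side)      # feints first
    ncross <- nu + nd
    for (cidx in seq_len(ncross)) {
      side <- if (side == below) above else below
      wp <- c(wp, side)
    }
    if (length(wp) == 1) wp <- c(wp, side)
    z <- unlist(lapply(seq_len(length(wp) - 1), function(j)
      seq(wp[j], wp[j + 1], length.out = samples_per_leg + 1)[-(samples_per_leg + 1)]))
    z <- c(z, wp[length(wp)])
    if (noise > 0) z <- z + rnorm(length(z), 0, noise)
    tibble(ion_id = i, species = schedule$species[i],
           time_ns = (seq_along(z) - 1) * dt_ns, z = z)
  })
  out <- ion_tracks(bind_rows(rows), slab)
  attr(out, "truth") <- schedule
  out
}

#' Biased random-walk ion tracks through a gated pore mouth
#'
#' Ions perform a z-biased random walk with lateral diffusion confined to a
#' cylinder; the upper slab face is passable only within `mouth_radius` of
#' the axis (attempted passes farther out are blocked). An ion that
#' completes a pass is recycled to the entry side, so the total up-crossing
#' count over the run measures the transport rate: shrinking the mouth
#' reduces, but does not zero, that count -- the permeation signature of a
#' partially occluded channel. (Recycling jumps register as down-crossings;
#' use the up counts.)
#'
#' @param n_ions Number of ions.
#' @param slab Membrane bounds.
#' @param cylinder_radius Lateral confinement radius (Angstrom).
#' @param mouth_radius Open radius of the gated upper face (Angstrom).
#' @param bias Upward drift velocity (Angstrom/ns).
#' @param d_ion Ion diffusion coefficient (A^2/ns).
#' @param dt_ns Timestep (default 0.05 ns).
#' @param n_steps Steps per ion.
#' @param species Ion species label.
#' @param seed RNG seed.
#' @return An [ion_tracks()] table.
#' @export
make_biased_walk_tracks <- function(n_ions = 50, slab = c(-20, 20),
                                    cylinder_radius = 10, mouth_radius = 10,
                                    bias = 20, d_ion = 50, dt_ns = 0.05,
                                    n_steps = 2000, species = "Na+",
                                    seed = 1L) {
  set.seed(seed)
  s <- sqrt(2 * d_ion * dt_ns)
  rows <- lapply(seq_len(n_ions), function(i) {
    z <- numeric(n_steps + 1); xy <- matrix(0, n_steps + 1, 2)
    z[1] <- slab[1] - 5
    th <- runif(1, 0, 2 * pi); r0 <- sqrt(runif(1)) * cylinder_radius
    xy[1, ] <- r0 * c(cos(th), sin(th))
    for (t in seq_len(n_steps)) {
      znew <- z[t] + bias * dt_ns + s * rnorm(1)
      xynew <- xy[t, ] + s * rnorm(2)
      rl <- sqrt(sum(xynew^2))
      if (rl > cylinder_radius) xynew <- xynew * (2 * cylinder_radius - rl) / rl
      # gated upper face: an attempted pass outside the open mouth is blocked
      if ((z[t] - slab[2]) * (znew - slab[2]) < 0 &&
          sqrt(sum(xynew^2)) > mouth_radius) {
        znew <- z[t]
      }
      if (znew > slab[2] + 8) znew <- slab[1] - 5   # recycle after a pass
      z[t + 1] <- znew; xy[t + 1, ] <- xynew
    }
    tibble(ion_id = i, species = species,
           time_ns = (0:n_steps) * dt_ns, z = z,
           x = xy[, 1], y = xy[, 2])
  })
  ion_tracks(bind_rows(rows), slab)
}

#' Atom-built cylindrical pore of known radius
#'
#' Atoms of vdW radius `atom_vdw` densely cover a cylinder of radius `R`, so
#' the true free-probe radius is `R - atom_vdw` at every interior slice. An
#' optional partial cap covers the upper mouth as an annulus from `R` inward
#' to `R * (1 - cap_fraction)`; `cap_fraction = 1` seals the mouth.
#'
#' @param R Cylinder radius (Angstrom).
#' @param atom_vdw vdW radius of the wall atoms (default 1.7 Angstrom).
#' @param z_height Cylinder height (Angstrom).
#' @param surface_spacing Approximate atom spacing on the surface
#'   (default 1 Angstrom).
#' @param cap_fraction Fraction (0-1) of the mouth radius occluded.
#' @param seed RNG seed (reserved; construction is deterministic).
#' @return A [bd_structure()]; attributes `R`, `atom_vdw`, `open_radius`
#'   carry the ground truth.
#' @export
make_cylinder_pore <- function(R = 12, atom_vdw = 1.7, z_height = 30,
                               surface_spacing = 1, cap_fraction = 0,
                               seed = 1L) {
  if (R <= 0 || z_height <= 0) abort("R and z_height must be positive")
  if (cap_fraction < 0 || cap_fraction > 1)
    abort("cap_fraction must be in [0, 1]")
  n_ring <- max(3, ceiling(2 * pi * R / surface_spacing))
  zs <- seq(-z_height / 2, z_height / 2, by = surface_spacing)
  ang <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  g <- expand.grid(a = ang, z = zs)
  pts <- cbind(R * cos(g$a), R * sin(g$a), g$z)
  if (cap_fraction > 0) {
    r_in <- R * (1 - cap_fraction)
    radii <- rev(seq(R, r_in, by = -surface_spacing))
    if (radii[1] > r_in + 1e-9) radii <- c(r_in, radii)
    cap <- do.call(rbind, lapply(radii, function(rr) {
      nr <- max(1, ceiling(2 * pi * max(rr, 1e-6) / surface_spacing))
      aa <- seq(0, 2 * pi, length.out = nr + 1)[-(nr + 1)]
      cbind(rr * cos(aa), rr * sin(aa), z_height / 2)
    }))
    pts <- rbind(pts, cap)
  }
  n <- nrow(pts)
  out <- bd_structure(tibble(
    serial = seq_len(n), name = "CW", element = "C", resname = "CYL",
    resid = seq_len(n), chain = "A",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    charge = 0, lj_rmin_half = 2.0, lj_epsilon = 0.1,
    vdw_radius = atom_vdw), title = "cylindrical pore")
  attr(out, "R") <- R
  attr(out, "atom_vdw") <- atom_vdw
  attr(out, "open_radius") <- max(0, R * (1 - cap_fraction) - atom_vdw)
  out
}
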