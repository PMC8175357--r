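# Overdamped rigid-body Brownian dynamics. The mobile body is a precomputed
# density cloud rigidly transformed each step; forces and torques come from
# the stationary body's grid maps, the anchor z-potentials and the lateral
# wall; propagation is the Ermak-McCammon update with isotropic translational
# and rotational diffusion.

#' Isotropic rigid-body diffusion model
#'
#' @param d_trans Translational diffusion coefficient, A^2/ns.
#' @param d_rot Rotational diffusion coefficient, rad^2/ns.
#' @param temperature Temperature in Kelvin (default 310).
#' @return A `diffusion_model` list.
#' @export
diffusion_model <- function(d_trans, d_rot, temperature = 310) {
  if (d_trans <= 0 || d_rot <= 0) abort("diffusion coefficients must be positive")
  if (temperature <= 0) abort("temperature must be positive")
  structure(list(d_trans = d_trans, d_rot = d_rot, temperature = temperature),
            class = "diffusion_model")
}

#' Stokes-Einstein diffusion model for a spherical body
#'
#' Fallback when bead-model friction coefficients are not supplied:
#' `D_trans = k_B T / (6 pi eta R)` and `D_rot = k_B T / (8 pi eta R^3)`,
#' converted to A^2/ns and rad^2/ns.
#'
#' @param radius Hydrodynamic radius in Angstrom.
#' @param viscosity Solvent viscosity in mPa s (0.6913 for water at 310 K).
#' @param temperature Temperature in Kelvin.
#' @return A [diffusion_model()].
#' @export
#' @examples
#' stokes_diffusion(20, 0.6913, 310)$d_trans # ~16.4 A^2/ns
stokes_diffusion <- function(radius, viscosity = 0.6913, temperature = 310) {
  if (radius <= 0 || viscosity <= 0 || temperature <= 0)
    abort("radius, viscosity and temperature must be positive")
  kb_si <- 1.380649e-23                    # J/K
  eta <- viscosity * 1e-3                  # Pa s
  r_m <- radius * 1e-10                    # m
  d_trans <- kb_si * temperature / (6 * pi * eta * r_m) * 1e11   # A^2/ns
  d_rot <- kb_si * temperature / (8 * pi * eta * r_m^3) * 1e-9   # rad^2/ns
  diffusion_model(d_trans, d_rot, temperature)
}

#' BD run parameters
#'
#' @param timestep_fs Integration timestep in femtoseconds (default 200).
#' @param duration_ns Run length per replica in nanoseconds.
#' @param output_stride_ns Interval between recorded frames (default 0.2).
#' @param cutoff Force cutoff in Angstrom (default 34; realised at
#'   map-construction time).
#' @param temperature Temperature in Kelvin (default 310).
#' @param seed Integer RNG seed recorded in the trajectory header.
#' @return A `bd_params` list.
#' @export
bd_params <- function(timestep_fs = 200, duration_ns, output_stride_ns = 0.2,
                      cutoff = 34, temperature = 310, seed = 1L) {
  if (timestep_fs <= 0) abort("timestep must be positive")
  if (duration_ns <= 0) abort("duration must be positive")
  structure(list(timestep_fs = timestep_fs, duration_ns = duration_ns,
                 output_stride_ns = output_stride_ns, cutoff = cutoff,
                 temperature = temperature, seed = as.integer(seed)),
            class = "bd_params")
}

#' Grid-map force and torque on a posed density cloud
#'
#' Each occupied density cell, rigidly transformed by the pose, feels the
#' negative gradient of the matching stationary map (charge density against
#' the electrostatic map, each category count density against its LJ map);
#' cell forces and their lever-arm torques about the body COM are summed.
#' A pure deterministic function of the pose.
#'
#' @param density A `density_set` from [build_density_set()].
#' @param maps A `map_set` from [build_map_set()].
#' @param pose Length-7 numeric `(x, y, z, qw, qx, qy, qz)` or a list with
#'   `t` and `q`.
#' @return List with `force` (kcal/mol/A) and `torque` (kcal/mol) 3-vectors.
#' @export
grid_force_torque <- function(density, maps, pose) {
  if (is.list(pose) && !is.null(pose$t)) pose <- c(pose$t, pose$q)
  pm <- pair_density_maps(density, maps)
  cpp_grid_force_torque(pm$maps, pm$cells, pose[1:3], pose[4:7])
}

#' One Ermak-McCammon update of a rigid-body state
#'
#' `dx = (D/k_BT) F dt + sqrt(2 D dt) xi` per axis, and a rotation vector
#' `dphi = (D_rot/k_BT) tau dt + sqrt(2 D_rot dt) xi` applied as an
#' exponential-map quaternion increment with renormalisation. With
#' `noise = FALSE` the update is the deterministic drift.
#'
#' @param state List with `t` (COM) and `q` (quaternion).
#' @param force,torque Length-3 vectors (kcal/mol/A, kcal/mol).
#' @param model A [diffusion_model()].
#' @param dt_ns Timestep in ns.
#' @param noise Include the thermal noise term?
#' @return The updated state.
#' @export
bd_step <- function(state, force, torque, model, dt_ns, noise = TRUE) {
  ktt <- kT(model$temperature)
  dx <- model$d_trans / ktt * force * dt_ns
  dphi <- model$d_rot / ktt * torque * dt_ns
  if (noise) {
    dx <- dx + sqrt(2 * model$d_trans * dt_ns) * rnorm(3)
    dphi <- dphi + sqrt(2 * model$d_rot * dt_ns) * rnorm(3)
  }
  q <- quat_multiply(quat_from_rotvec(dphi), state$q)
  list(t = state$t + dx, q = q / sqrt(sum(q^2)))
}

#' Run rigid-body BD replicas
#'
#' Propagates one or more independent replicas of the mobile body in the
#' stationary body's grid maps under anchor restraints and the confinement
#' wall. Identical seed and inputs give a bit-identical trajectory.
#'
#' @param density `density_set` of the mobile body (may be `NULL` together
#'   with `maps` for free diffusion).
#' @param maps `map_set` of the stationary body (or `NULL`).
#' @param model A [diffusion_model()].
#' @param params A [bd_params()].
#' @param initial_poses Matrix with one row per replica:
#'   `(x, y, z, qw, qx, qy, qz)`.
#' @param restraints Optional [restraint_set()].
#' @param anchors Tibble with columns `label`, `x`, `y`, `z`: body-frame
#'   anchor positions (same frame as the mobile structure) matching the
#'   restraint potentials by label. Required when `restraints` carries
#'   potentials.
#' @param noise Thermal noise on (`TRUE`) or off for deterministic checks.
#' @param cap Energy cap used for the initial-overlap check (kcal/mol).
#' @return A [bd_trajectory()] with a `replica` column; attributes record
#'   the seed, parameters and map provenance.
#' @export
run_bd <- function(density, maps, model, params, initial_poses,
                   restraints = NULL, anchors = NULL, noise = TRUE, cap = 30) {
  if (is.null(dim(initial_poses))) initial_poses <- matrix(initial_poses, nrow = 1)
  if (ncol(initial_poses) != 7) abort("initial poses need 7 columns (x, y, z, qw, qx, qy, qz)")
  dt_ns <- params$timestep_fs * 1e-6
  out_every <- max(1L, as.integer(round(params$output_stride_ns / dt_ns)))
  nsteps <- as.integer(round(params$duration_ns / dt_ns))
  nsteps <- (nsteps %/% out_every) * out_every
  if (nsteps < 1) abort("duration shorter than one output stride")

  if (!is.null(density) && !is.null(maps)) {
    pm <- pair_density_maps(density, maps)
    com <- density$com
  } else {
    pm <- list(maps = list(), cells = list())
    com <- c(0, 0, 0)
  }

  rl <- list()
  if (!is.null(restraints) && length(restraints$potentials) > 0) {
    if (is.null(anchors)) abort("anchor positions are required with residue restraints")
    for (lab in names(restraints$potentials)) {
      arow <- anchors[anchors$label == lab, ]
      if (nrow(arow) != 1)
        abort(paste0("no anchor position for restraint label '", lab, "'"))
      pot <- restraints$potentials[[lab]]
      dz <- round(diff(pot$z[1:2]), 10)
      rl[[length(rl) + 1]] <- list(
        b = c(arow$x, arow$y, arow$z) - com,
        z0 = pot$z[1], dz = dz, U = pot$U)
    }
  }
  wall <- if (!is.null(restraints) && is.finite(restraints$wall_radius)) {
    list(cx = restraints$wall_center[1], cy = restraints$wall_center[2],
         radius = restraints$wall_radius, stiffness = restraints$wall_stiffness)
  } else list()

  # reject initial poses already clashing with the stationary body
  if (length(pm$maps) > 1) {
    for (r in seq_len(nrow(initial_poses))) {
      pose <- initial_poses[r, ]
      for (m in seq_along(pm$maps)[-1]) {
        pts <- pose_apply(pm$cells[[m]]$pos, pose[1:3], pose[4:7])
        vals <- cpp_grid_interp(pm$maps[[m]][c("dim", "origin", "spacing")],
                                pm$maps[[m]]$values, pts, 0L)
        if (any(vals > cap / 2))
          abort(paste0("initial pose of replica ", r,
                       " overlaps the stationary body (LJ energy above cap/2)"))
      }
    }
  }

  set.seed(params$seed)
  ktt <- kT(params$temperature)
  runs <- lapply(seq_len(nrow(initial_poses)), function(r) {
    m <- cpp_run_bd(pm$maps, pm$cells, rl, wall,
                    model$d_trans, model$d_rot, ktt, dt_ns,
                    nsteps, out_every,
                    initial_poses[r, 1:3], initial_poses[r, 4:7], noise)
    tibble(replica = r, time_ns = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4],
           qw = m[, 5], qx = m[, 6], qy = m[, 7], qz = m[, 8])
  })
  traj <- bd_trajectory(bind_rows(runs))
  attr(traj, "seed") <- params$seed
  attr(traj, "params") <- params
  attr(traj, "provenance") <- if (!is.null(maps)) maps$provenance else "none"
  traj
}
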