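# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's grid/spatial-hash code paths: they are direct pairwise
# sums and double loops used to check the fast implementations.

# a random blob body with mixed elements, charges and LJ parameters; an
# optional net charge mimics the monopole of a charged protein (a nearly
# neutral blob has a cancelling net force, which makes relative force errors
# ill-conditioned)
make_random_body <- function(n, rad, seed, net_charge = NULL) {
  set.seed(seed)
  el <- sample(c("C", "O", "N", "H", "S"), n, replace = TRUE)
  pts <- matrix(rnorm(n * 3), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * rad * runif(n)^(1 / 3)
  bd_structure(tibble::tibble(
    serial = seq_len(n), name = el, element = el, resname = "TOY",
    resid = seq_len(n), chain = "A",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    charge = round(runif(n, -0.5, 0.5), 3),
    lj_rmin_half = ifelse(el == "H", 1.2, 2.0),
    lj_epsilon = ifelse(el == "H", 0.03, 0.12),
    vdw_radius = 1.6))
}

charged_random_body <- function(n, rad, seed, net_charge) {
  b <- make_random_body(n, rad, seed)
  b$charge <- b$charge + (net_charge - sum(b$charge)) / n
  b
}

# one-atom structure helper
point_structure <- function(x, y, z, charge = 0, rmin_half = 0, eps = 0,
                            vdw = 1.5, element = "C", serial = seq_along(x)) {
  bd_structure(tibble::tibble(
    serial = as.integer(serial), name = element, element = element,
    resname = "PT", resid = seq_along(x), chain = "A",
    x = x, y = y, z = z, charge = charge,
    lj_rmin_half = rmin_half, lj_epsilon = eps, vdw_radius = vdw))
}

# lab-frame coordinates of a body under a pose (about its geometric COM)
posed_coords <- function(body, pose) {
  com <- structure_com(body)
  R <- quat_to_matrix(pose[4:7])
  xm <- sweep(cbind(body$x, body$y, body$z), 2, com) %*% t(R)
  sweep(xm, 2, pose[1:3], "+")
}

# direct pairwise Coulomb + category-LJ force/torque oracle mirroring the
# grid model's physics (uniform dielectric, category probe parameters,
# Lorentz-Berthelot), summed atom by atom
pairwise_force_oracle <- function(mobile, stationary, pose, categories,
                                  eps_s, cutoff = 34) {
  xm <- posed_coords(mobile, pose)
  xs <- cbind(stationary$x, stationary$y, stationary$z)
  catm <- c(H = "H", O = "ON", N = "ON", C = "CS", S = "CS")[mobile$element]
  F <- c(0, 0, 0); tau <- c(0, 0, 0)
  for (a in seq_len(nrow(mobile))) {
    cr <- categories[categories$label == catm[a], ]
    for (b in seq_len(nrow(stationary))) {
      d <- xm[a, ] - xs[b, ]
      r <- sqrt(sum(d^2))
      if (r > cutoff) next
      f <- 332.0636 * mobile$charge[a] * stationary$charge[b] /
        (eps_s * r^2) * d / r
      rij <- stationary$lj_rmin_half[b] + cr$rmin_mean / 2
      eij <- sqrt(stationary$lj_epsilon[b] * cr$eps_scaled)
      s6 <- (rij / r)^6
      f <- f + 12 * eij / r * (s6^2 - s6) * d / r
      F <- F + f
      rel <- xm[a, ] - pose[1:3]
      tau <- tau + c(rel[2] * f[3] - rel[3] * f[2],
                     rel[3] * f[1] - rel[1] * f[3],
                     rel[1] * f[2] - rel[2] * f[1])
    }
  }
  list(force = F, torque = tau)
}

# brute-force O(N^2) minimum inter-body distance
brute_min_dist <- function(mobile, stationary, pose) {
  xm <- posed_coords(mobile, pose)
  xs <- cbind(stationary$x, stationary$y, stationary$z)
  min(sqrt(outer(rowSums(xm^2), rep(1, nrow(xs))) +
             outer(rep(1, nrow(xm)), rowSums(xs^2)) - 2 * xm %*% t(xs)))
}

# brute-force RMSD between two posed frames over reference coordinates
brute_rmsd <- function(ref, com, pose_i, pose_j) {
  C <- sweep(ref, 2, com)
  xi <- sweep(C %*% t(quat_to_matrix(pose_i[4:7])), 2, pose_i[1:3], "+")
  xj <- sweep(C %*% t(quat_to_matrix(pose_j[4:7])), 2, pose_j[1:3], "+")
  sqrt(mean(rowSums((xi - xj)^2)))
}

# simple trajectory wrapper around a poses matrix
traj_from_poses <- function(P) {
  bd_trajectory(tibble::tibble(
    time_ns = seq_len(nrow(P)) * 0.2,
    x = P[, 1], y = P[, 2], z = P[, 3],
    qw = P[, 4], qx = P[, 5], qy = P[, 6], qz = P[, 7]))
}

random_unit_quats <- function(n) t(replicate(n, quat_random()))

# membrane-aligned toy association system shared by the end-to-end tests
build_association_system <- function(site_angle_deg, seed = 7, n_replicas = 20,
                                     duration_ns = 60) {
  sta <- make_toy_barrel(radius = 15, height = 35, rim_frac = 0.5,
                         rim_charge = 0, site_charge = -0.5,
                         site_angle_deg = site_angle_deg,
                         site_halfwidth_deg = 30)
  mob <- make_anchor_probe(n_atoms = 20, head_charge = 1)
  mob$z <- mob$z + align_membrane_frames(mob$z[1], 0)
  anch_tbl <- attr(mob, "anchors")
  pots <- list(); anchors <- NULL
  for (i in seq_len(nrow(anch_tbl))) {
    sel <- mob$resid == anch_tbl$resid[i]
    z0 <- mean(mob$z[sel])
    zs <- sample_anchored_z(1.0, z0, 2e4, 310, seed = 100 + i)
    pots[[anch_tbl$label[i]]] <- boltzmann_invert(zs, 310)
    anchors <- rbind(anchors, data.frame(
      label = anch_tbl$label[i], x = mean(mob$x[sel]), y = mean(mob$y[sel]),
      z = z0))
  }
  rs <- restraint_set(pots, wall_radius = 60, wall_stiffness = 10)
  frame <- grid_frame(sta, margin = 40, spacing = 1)
  maps <- suppressWarnings(build_map_set(
    sta, frame = frame, cutoff = 34, cap = 30, solvent_dielectric = 4,
    ionic_strength = 0))
  dens <- build_density_set(mob)
  model <- stokes_diffusion(12, 0.6913, 310)
  params <- bd_params(timestep_fs = 200, duration_ns = duration_ns,
                      output_stride_ns = 0.2, seed = seed)
  theta <- 2 * pi * (seq_len(n_replicas) - 1) / n_replicas
  init <- cbind(40 * cos(theta), 40 * sin(theta), dens$com[3], 1, 0, 0, 0)
  traj <- run_bd(dens, maps, model, params, init, restraints = rs,
                 anchors = tibble::as_tibble(anchors))
  list(traj = traj, mobile = mob, stationary = sta,
       anchors = tibble::as_tibble(anchors), site_angle = site_angle_deg)
}
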