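# Turning BD trajectories into complexes: contact detection, greedy
# quality-threshold RMSD clustering, interaction energies, anchor-COM
# hot-spot densities, tilt angles, insertion depths, and phosphomimetic
# charge-perturbation rescoring.

# rotate a single body-frame point by every frame's quaternion (vectorised:
# p' = p + 2 w (v x p) + 2 v x (v x p))
rotate_point_frames <- function(Q, p) {
  w <- Q[, 1]; vx <- Q[, 2]; vy <- Q[, 3]; vz <- Q[, 4]
  cx <- vy * p[3] - vz * p[2]
  cy <- vz * p[1] - vx * p[3]
  cz <- vx * p[2] - vy * p[1]
  ccx <- vy * cz - vz * cy
  ccy <- vz * cx - vx * cz
  ccz <- vx * cy - vy * cx
  cbind(p[1] + 2 * (w * cx + ccx),
        p[2] + 2 * (w * cy + ccy),
        p[3] + 2 * (w * cz + ccz))
}

# lab-frame positions of one body point across all frames
point_positions <- function(traj, point, com) {
  P <- poses_matrix(traj)
  rotate_point_frames(P[, 4:7, drop = FALSE], point - com) + P[, 1:3, drop = FALSE]
}

#' Frames in which the two bodies are in contact
#'
#' A frame is in contact when the minimum inter-body atom distance after the
#' rigid transform is at most `cutoff` (default 3 Angstrom). Uses a
#' spatial-hash neighbour search equal in result to the brute-force double
#' loop.
#'
#' @param traj A [bd_trajectory()].
#' @param mobile,stationary [bd_structure()] objects; the trajectory poses
#'   act on the mobile body about its geometric COM.
#' @param cutoff Contact cutoff in Angstrom.
#' @return Integer vector of frame (row) indices in contact.
#' @export
contact_frames <- function(traj, mobile, stationary, cutoff = 3.0) {
  mob_rel <- sweep(coords_matrix(mobile), 2, structure_com(mobile))
  hit <- cpp_contact_frames(poses_matrix(traj), mob_rel,
                            coords_matrix(stationary), cutoff)
  which(hit)
}

#' Pairwise pose RMSD matrix
#'
#' RMSD between frames of the mobile body's reference atoms expressed in the
#' stationary frame (no refitting: the stationary body defines the
#' superposition). Computed with the rigid-body identity
#' `K d_ij^2 = 2 tr(S) - 2 vec(R_i S) . vec(R_j) + 2 (t_i - t_j).(R_i - R_j) m + K |t_i - t_j|^2`
#' where `S` is the second-moment matrix and `m` the first moment of the
#' reference coordinates, so no per-atom loop over frame pairs is needed.
#'
#' @param traj A [bd_trajectory()] (or subset of rows).
#' @param ref_coords n x 3 matrix of reference (e.g. C-alpha) coordinates in
#'   the body frame, or a [bd_structure()].
#' @param com Body COM the poses rotate about; defaults to the mean of
#'   `ref_coords` when a structure is given, which must match the COM used
#'   for the run (the full structure's COM).
#' @return F x F symmetric matrix of RMSDs (Angstrom).
#' @export
pose_rmsd_matrix <- function(traj, ref_coords, com = NULL) {
  if (inherits(ref_coords, "bd_structure")) {
    if (is.null(com)) com <- structure_com(ref_coords)
    ref_coords <- coords_matrix(ref_coords)
  }
  if (is.null(com)) com <- c(0, 0, 0)
  C <- sweep(ref_coords, 2, com)
  K <- nrow(C)
  S <- crossprod(C)                      # sum c c^T
  m <- colSums(C)
  P <- poses_matrix(traj)
  Tm <- P[, 1:3, drop = FALSE]
  F <- nrow(P)
  Rv <- matrix(0, F, 9)
  PS <- matrix(0, F, 9)
  U <- matrix(0, F, 3)
  for (f in seq_len(F)) {
    R <- quat_to_matrix(P[f, 4:7])
    Rv[f, ] <- as.numeric(R)
    PS[f, ] <- as.numeric(R %*% S)
    U[f, ] <- as.numeric(R %*% m)
  }
  cross <- PS %*% t(Rv)                  # tr(R_i S R_j^T)
  tu <- rowSums(Tm * U)
  TU <- Tm %*% t(U)
  t2 <- rowSums(Tm^2)
  TT <- Tm %*% t(Tm)
  d2 <- (2 * sum(diag(S)) - 2 * cross +
           2 * (outer(tu, rep(1, F)) - TU - t(TU) + outer(rep(1, F), tu))) / K +
    outer(t2, rep(1, F)) + outer(rep(1, F), t2) - 2 * TT
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  sqrt(d2)
}

#' Greedy quality-threshold clustering of poses
#'
#' Repeatedly takes the frame with the most neighbours within `rmsd_cutoff`
#' as a cluster seed (earliest index on ties), assigns its neighbours,
#' removes them, and repeats. Clusters are ordered by size; populations are
#' fractions of the frames given (typically the in-contact frames).
#'
#' @inheritParams pose_rmsd_matrix
#' @param frames Optional integer subset of trajectory rows to cluster
#'   (e.g. from [contact_frames()]); defaults to all rows.
#' @param rmsd_cutoff Neighbour cutoff in Angstrom (default 10).
#' @param energies Optional tibble with columns `frame`, `elec`, `vdw`
#'   (kcal/mol) used to pick each cluster's representative as the member
#'   with the most favourable (lowest) total interaction energy; without
#'   it the seed frame is the representative.
#' @return A `pose_clusters` tibble: one row per cluster with `cluster`,
#'   `n`, `population`, `representative` (frame index), `frames` (list
#'   column) and, when energies are given, `rep_elec` and `rep_vdw`.
#' @export
cluster_poses <- function(traj, ref_coords, rmsd_cutoff = 10, frames = NULL,
                          com = NULL, energies = NULL) {
  if (is.null(frames)) frames <- seq_len(nrow(traj))
  if (length(frames) == 0) {
    return(structure(tibble(cluster = integer(), n = integer(),
                            population = numeric(), representative = integer(),
                            frames = list()),
                     class = c("pose_clusters", class(tibble()))))
  }
  sub <- traj[frames, , drop = FALSE]
  D <- pose_rmsd_matrix(sub, ref_coords, com = com)
  adj <- D <= rmsd_cutoff
  remaining <- rep(TRUE, length(frames))
  members <- list()
  while (any(remaining)) {
    counts <- rowSums(adj[, remaining, drop = FALSE]) * remaining
    seed <- which.max(counts)            # earliest index wins ties
    grp <- which(adj[seed, ] & remaining)
    members[[length(members) + 1]] <- list(seed = seed, idx = grp)
    remaining[grp] <- FALSE
  }
  ord <- order(-vapply(members, function(m) length(m$idx), integer(1)),
               vapply(members, function(m) m$seed, integer(1)))
  rows <- lapply(seq_along(ord), function(ci) {
    m <- members[[ord[ci]]]
    fr <- frames[m$idx]
    rep_frame <- frames[m$seed]
    rep_e <- c(NA_real_, NA_real_)
    if (!is.null(energies)) {
      e <- energies[match(fr, energies$frame), ]
      tot <- e$elec + e$vdw
      best <- which.min(tot)
      rep_frame <- fr[best]
      rep_e <- c(e$elec[best], e$vdw[best])
    }
    tibble(cluster = ci, n = length(fr),
           population = length(fr) / length(frames),
           representative = rep_frame, frames = list(fr),
           rep_elec = rep_e[1], rep_vdw = rep_e[2])
  })
  out <- bind_rows(rows)
  if (is.null(energies)) out$rep_elec <- out$rep_vdw <- NULL
  structure(out, class = c("pose_clusters", class(tibble())))
}

#' Pairwise inter-body interaction energy at one pose
#'
#' Coulomb (`332.0636 q_i q_j / (eps_r r)`) plus Lennard-Jones
#' (Rmin convention, Lorentz-Berthelot combination) summed over inter-body
#' pairs within a hard cutoff; no switching function.
#'
#' @param mobile,stationary [bd_structure()] objects with charges and LJ
#'   parameters.
#' @param pose Length-7 pose of the mobile body (about its geometric COM).
#' @param eps_r Relative dielectric (default 1).
#' @param cutoff Pair cutoff in Angstrom (default 12).
#' @param charges_stationary Optional replacement charge vector for the
#'   stationary body (used by the phosphomimetic rescoring).
#' @return One-row tibble with `elec` and `vdw` in kcal/mol.
#' @export
interaction_energy <- function(mobile, stationary, pose, eps_r = 1,
                               cutoff = 12, charges_stationary = NULL) {
  mob <- pose_apply(sweep(coords_matrix(mobile), 2, structure_com(mobile)),
                    pose[1:3], pose[4:7])
  qs <- charges_stationary %||% stationary$charge
  e <- cpp_pair_energy(mob, mobile$charge, mobile$lj_rmin_half,
                       mobile$lj_epsilon, coords_matrix(stationary), qs,
                       stationary$lj_rmin_half, stationary$lj_epsilon,
                       eps_r, cutoff)
  tibble(elec = e[1], vdw = e[2])
}

#' Interaction energies along a trajectory
#'
#' @inheritParams interaction_energy
#' @param traj A [bd_trajectory()].
#' @param frames Frame (row) indices to score; defaults to all.
#' @return Tibble with columns `frame`, `elec`, `vdw`.
#' @export
trajectory_energies <- function(traj, mobile, stationary, frames = NULL,
                                eps_r = 1, cutoff = 12,
                                charges_stationary = NULL) {
  if (is.null(frames)) frames <- seq_len(nrow(traj))
  P <- poses_matrix(traj)
  rows <- lapply(frames, function(f)
    interaction_energy(mobile, stationary, P[f, ], eps_r, cutoff,
                       charges_stationary))
  dplyr::bind_cols(tibble(frame = frames), bind_rows(rows))
}

#' Hot-spot density of the anchor COM over the membrane plane
#'
#' Gaussian kernel density of the (x, y) position of a body selection's COM
#' across frames, on a 1 Angstrom grid, normalised to integrate to 1.
#' Default bandwidth is Scott's rule (`sd * n^(-1/6)` per axis, floored at
#' 0.5 Angstrom).
#'
#' @param traj A [bd_trajectory()].
#' @param mobile The mobile [bd_structure()].
#' @param selection Integer/logical row selection of the anchor atoms.
#' @param bandwidth Optional kernel sd (scalar or length-2, Angstrom).
#' @param frames Optional frame subset.
#' @param resolution Grid spacing (default 1 Angstrom).
#' @return A `hotspot_density` object (list with `x`, `y`, `density` matrix,
#'   `bandwidth`).
#' @export
hotspot_density <- function(traj, mobile, selection, bandwidth = NULL,
                            frames = NULL, resolution = 1) {
  if (is.null(frames)) frames <- seq_len(nrow(traj))
  if (length(frames) < 10) abort("hotspot density needs at least 10 frames")
  sel_com <- colMeans(coords_matrix(mobile)[selection, , drop = FALSE])
  pos <- point_positions(traj[frames, ], sel_com, structure_com(mobile))
  n <- nrow(pos)
  if (is.null(bandwidth)) {
    bandwidth <- pmax(c(sd(pos[, 1]), sd(pos[, 2])) * n^(-1 / 6), 0.5)
  }
  if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  pad <- 3 * max(bandwidth) + resolution
  lims <- c(range(pos[, 1]) + c(-pad, pad), range(pos[, 2]) + c(-pad, pad))
  np <- c(ceiling(diff(lims[1:2]) / resolution) + 1,
          ceiling(diff(lims[3:4]) / resolution) + 1)
  kd <- MASS::kde2d(pos[, 1], pos[, 2], h = 4 * bandwidth, n = np, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  dens <- kd$z / (sum(kd$z) * dx * dy)
  structure(list(x = kd$x, y = kd$y, density = dens,
                 bandwidth = bandwidth, cell = c(dx, dy)),
            class = "hotspot_density")
}

#' Location of the highest-density point
#' @param hd A [hotspot_density()].
#' @return Length-2 (x, y) of the density mode.
#' @export
hotspot_peak <- function(hd) {
  ij <- which(hd$density == max(hd$density), arr.ind = TRUE)[1, ]
  c(hd$x[ij[1]], hd$y[ij[2]])
}

#' @export
print.hotspot_density <- function(x, ...) {
  cat("# hotspot_density: ", length(x$x), " x ", length(x$y),
      " grid, bandwidth (", paste(signif(x$bandwidth, 3), collapse = ", "),
      ") A, peak at (", paste(signif(hotspot_peak(x), 4), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Phosphomimetic charge-perturbation rescoring
#'
#' Recomputes each cluster's mean electrostatic interaction energy with the
#' atoms of one stationary-body residue carrying modified charges (e.g.
#' phosphoserine in place of serine) and reports the ratio
#' original/modified per cluster: values above 1 mean the modification
#' weakens the attraction.
#'
#' @param traj A [bd_trajectory()].
#' @param mobile,stationary [bd_structure()] objects.
#' @param clusters A `pose_clusters` tibble from [cluster_poses()].
#' @param site_resid Residue id of the modified site in the stationary body.
#' @param modified_charges Numeric vector of new charges for the site's
#'   atoms, in structure order (or named by atom name).
#' @param eps_r,cutoff Passed to [interaction_energy()].
#' @return Tibble with `cluster`, `elec_original`, `elec_modified`, `ratio`.
#' @export
phospho_rescore <- function(traj, mobile, stationary, clusters, site_resid,
                            modified_charges, eps_r = 1, cutoff = 12) {
  sel <- which(stationary$resid == site_resid)
  if (length(sel) == 0)
    abort(paste0("residue id ", site_resid, " not found in stationary body"))
  qmod <- stationary$charge
  if (!is.null(names(modified_charges))) {
    hit <- match(stationary$name[sel], names(modified_charges))
    if (anyNA(hit)) abort("modified charges missing for some site atoms")
    qmod[sel] <- modified_charges[hit]
  } else {
    if (length(modified_charges) != length(sel))
      abort("modified_charges length does not match the site's atom count")
    qmod[sel] <- modified_charges
  }
  rows <- lapply(seq_len(nrow(clusters)), function(ci) {
    fr <- clusters$frames[[ci]]
    e0 <- trajectory_energies(traj, mobile, stationary, fr, eps_r, cutoff)
    e1 <- trajectory_energies(traj, mobile, stationary, fr, eps_r, cutoff,
                              charges_stationary = qmod)
    m0 <- mean(e0$elec); m1 <- mean(e1$elec)
    ratio <- if (abs(m0 - m1) < 1e-12) 1.0 else m0 / m1
    tibble(cluster = clusters$cluster[ci], elec_original = m0,
           elec_modified = m1, ratio = ratio)
  })
  bind_rows(rows)
}

#' Tilt angle of a body axis relative to the membrane normal
#'
#' The axis runs from the COM of `selection1` to the COM of `selection2`;
#' the angle is measured against +z, in degrees within \[0, 180\].
#'
#' @param traj A [bd_trajectory()].
#' @param mobile The mobile [bd_structure()].
#' @param selection1,selection2 Row selections defining the axis endpoints.
#' @return Tibble with `frame`, `time_ns`, `tilt_deg`.
#' @export
tilt_angle <- function(traj, mobile, selection1, selection2) {
  C <- coords_matrix(mobile)
  p1 <- colMeans(C[selection1, , drop = FALSE])
  p2 <- colMeans(C[selection2, , drop = FALSE])
  axis <- p2 - p1
  if (sqrt(sum(axis^2)) < 1e-9) abort("selection COMs coincide: no axis defined")
  Q <- poses_matrix(traj)[, 4:7, drop = FALSE]
  v <- rotate_point_frames(Q, axis)
  ang <- acos(pmin(1, pmax(-1, v[, 3] / sqrt(rowSums(v^2))))) * 180 / pi
  tibble(frame = seq_len(nrow(traj)), time_ns = traj$time_ns, tilt_deg = ang)
}

#' Per-residue membrane insertion depth
#'
#' Signed z of each selection's COM relative to the phosphorus plane
#' (negative = below the plane, i.e. inserted), averaged over frames.
#'
#' @param traj A [bd_trajectory()].
#' @param mobile The mobile [bd_structure()].
#' @param selections Named list of row selections (one per residue).
#' @param phosphorus_plane_z z of the phosphorus plane (Angstrom).
#' @param frames Optional frame subset.
#' @return Tibble with `residue`, `mean_depth`, `sd_depth` (Angstrom).
#' @export
membrane_depth_profile <- function(traj, mobile, selections,
                                   phosphorus_plane_z, frames = NULL) {
  if (!is.finite(phosphorus_plane_z)) abort("phosphorus plane z must be finite")
  if (is.null(frames)) frames <- seq_len(nrow(traj))
  com <- structure_com(mobile)
  C <- coords_matrix(mobile)
  rows <- imap(selections, function(sel, nm) {
    if (length(sel) == 0 || (is.logical(sel) && !any(sel)))
      abort(paste0("empty selection for residue '", nm, "'"))
    p <- colMeans(C[sel, , drop = FALSE])
    zs <- point_positions(traj[frames, ], p, com)[, 3] - phosphorus_plane_z
    tibble(residue = nm, mean_depth = mean(zs),
           sd_depth = if (length(zs) > 1) sd(zs) else 0)
  })
  bind_rows(rows)
}
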