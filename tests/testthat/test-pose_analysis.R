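test_that("contact detection respects the 3 A cutoff", {
  a <- point_structure(0, 0, 0)
  b29 <- point_structure(0, 0, 0)
  tr <- traj_from_poses(rbind(c(2.9, 0, 0, 1, 0, 0, 0),
                              c(3.1, 0, 0, 1, 0, 0, 0)))
  expect_equal(contact_frames(tr, b29, a, cutoff = 3.0), 1L)
})

test_that("spatial-hash contact search equals the brute-force double loop", {
  sta <- make_random_body(250, 12, seed = 91)
  mob <- make_random_body(250, 8, seed = 92)
  set.seed(93)
  poses <- t(sapply(1:50, function(i) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    c(v * runif(1, 15, 26), quat_random())
  }))
  tr <- traj_from_poses(poses)
  fast <- contact_frames(tr, mob, sta, cutoff = 3.0)
  brute <- which(sapply(seq_len(nrow(poses)), function(i)
    brute_min_dist(mob, sta, poses[i, ]) <= 3.0))
  expect_equal(fast, brute)
  expect_gt(length(brute), 0)       # the pose set actually spans the cutoff
  expect_lt(length(brute), nrow(poses))
})

test_that("pose RMSD matrix matches the per-atom brute force", {
  ref <- cbind(rnorm(12, 0, 3), rnorm(12, 0, 3), rnorm(12, 0, 3))
  com <- colMeans(ref)
  set.seed(94)
  poses <- t(sapply(1:8, function(i) c(rnorm(3, 0, 10), quat_random())))
  D <- pose_rmsd_matrix(traj_from_poses(poses), ref, com = com)
  for (i in 1:8) for (j in 1:8)
    expect_equal(D[i, j], brute_rmsd(ref, com, poses[i, ], poses[j, ]),
                 tolerance = 1e-6)
})

test_that("quality-threshold clustering separates pose blobs", {
  ref <- cbind(rnorm(10, 0, 2), rnorm(10, 0, 2), rnorm(10, 0, 2))
  com <- colMeans(ref)
  # all frames identical: one cluster
  same <- traj_from_poses(matrix(rep(c(5, 0, 0, 1, 0, 0, 0), 7),
                                 ncol = 7, byrow = TRUE))
  cl <- cluster_poses(same, ref, rmsd_cutoff = 10, com = com)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n, 7)
  expect_equal(cl$population, 1)

  # two tight blobs 40 A apart: exactly two clusters with right memberships
  set.seed(95)
  blob <- function(center, n) t(sapply(seq_len(n), function(i)
    c(center + rnorm(3, 0, 2 / sqrt(3)), 1, 0, 0, 0)))
  P <- rbind(blob(c(0, 0, 0), 12), blob(c(40, 0, 0), 9))
  cl2 <- cluster_poses(traj_from_poses(P), ref, rmsd_cutoff = 10, com = com)
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$n, c(12, 9))
  expect_setequal(cl2$frames[[1]], 1:12)
  expect_setequal(cl2$frames[[2]], 13:21)

  # empty input: empty result
  expect_equal(nrow(cluster_poses(traj_from_poses(P), ref, frames = integer(),
                                  com = com)), 0)
})

test_that("clustering recovers five generative blobs and survives permutation", {
  skip_if_not_installed("mclust")
  ref <- cbind(rnorm(10, 0, 2), rnorm(10, 0, 2), rnorm(10, 0, 2))
  com <- colMeans(ref)
  set.seed(96)
  centers <- 45 * cbind(cos(2 * pi * (0:4) / 5), sin(2 * pi * (0:4) / 5), 0)
  P <- do.call(rbind, lapply(1:5, function(b) t(sapply(1:30, function(i)
    c(centers[b, ] + rnorm(3, 0, 1.5), quat_from_rotvec(rnorm(3, 0, 0.02)))))))
  labels <- rep(1:5, each = 30)
  cl <- cluster_poses(traj_from_poses(P), ref, rmsd_cutoff = 10, com = com)
  expect_equal(nrow(cl), 5)
  got <- integer(150)
  for (ci in seq_len(nrow(cl))) got[cl$frames[[ci]]] <- ci
  expect_equal(mclust::adjustedRandIndex(got, labels), 1.0)

  # frame order permutation changes memberships not at all (well-separated)
  perm <- sample(150)
  clp <- cluster_poses(traj_from_poses(P[perm, ]), ref, rmsd_cutoff = 10,
                       com = com)
  gotp <- integer(150)
  for (ci in seq_len(nrow(clp))) gotp[perm[clp$frames[[ci]]]] <- ci
  expect_equal(mclust::adjustedRandIndex(gotp, got), 1.0)
})

test_that("interaction energy reproduces Coulomb arithmetic and symmetry", {
  a <- point_structure(0, 0, 0, charge = 1)
  b <- point_structure(0, 0, 0, charge = 1)
  e <- interaction_energy(b, a, c(10, 0, 0, 1, 0, 0, 0), eps_r = 1,
                          cutoff = 12)
  expect_equal(e$elec, 33.20636, tolerance = 1e-6)
  expect_equal(e$vdw, 0)

  bneg <- point_structure(0, 0, 0, charge = -1)
  e2 <- interaction_energy(bneg, a, c(10, 0, 0, 1, 0, 0, 0), eps_r = 1,
                           cutoff = 12)
  expect_equal(e2$elec, -e$elec)

  efar <- interaction_energy(b, a, c(13, 0, 0, 1, 0, 0, 0), eps_r = 1,
                             cutoff = 12)
  expect_equal(unlist(efar), c(elec = 0, vdw = 0))

  # LJ pair at its minimum distance
  al <- point_structure(0, 0, 0, rmin_half = 2, eps = 0.1)
  bl <- point_structure(0, 0, 0, rmin_half = 2, eps = 0.1)
  el <- interaction_energy(bl, al, c(4, 0, 0, 1, 0, 0, 0), cutoff = 12)
  expect_equal(el$vdw, -0.1, tolerance = 1e-12)

  expect_error(interaction_energy(b, a, c(0.05, 0, 0, 1, 0, 0, 0)),
               "0.1 A")
})

test_that("grid energy converges to the pairwise sum as spacing shrinks", {
  # two-charge toy: probe density against the stationary charge's map
  sta <- point_structure(0, 0, 0, charge = 1)
  mob <- point_structure(0, 0, 0, charge = 1)
  pose <- c(7.3, 2.1, 1.4, 1, 0, 0, 0)
  exact <- interaction_energy(mob, sta, pose, eps_r = 78, cutoff = 34)$elec
  err <- sapply(c(1, 0.5, 0.25), function(h) {
    frame <- list(origin = c(-12, -12, -12), spacing = rep(h, 3),
                  dim = rep(as.integer(24 / h) + 1L, 3))
    m <- screened_coulomb_map(sta, frame, solvent_dielectric = 78,
                              ionic_strength = 0, cutoff = 34, cap = 1e5)
    dens <- build_density_set(mob, spacing = h)
    cl <- which(dens$charge$values != 0, arr.ind = TRUE)
    pos <- cbind(dens$charge$origin[1] + (cl[, 1] - 1) * h - dens$com[1],
                 dens$charge$origin[2] + (cl[, 2] - 1) * h - dens$com[2],
                 dens$charge$origin[3] + (cl[, 3] - 1) * h - dens$com[3])
    pts <- sweep(pos, 2, pose[1:3], "+")
    abs(sum(dens$charge$values[cl] * interpolate(m, pts)) - exact) / abs(exact)
  })
  expect_lt(err[3], 0.02)
  expect_true(all(diff(err) < 0))
})

test_that("hot-spot densities are normalised, non-negative, mode-faithful", {
  mob <- make_anchor_probe()
  # all frames at one (x, y): single peak there, integral 1
  P <- matrix(rep(c(12, -7, 0, 1, 0, 0, 0), 20), ncol = 7, byrow = TRUE)
  hd <- hotspot_density(traj_from_poses(P), mob, selection = 1:20)
  expect_true(all(hd$density >= 0))
  expect_equal(glance(hd)$integral, 1, tolerance = 1e-6)
  com <- structure_com(mob)
  expect_equal(hotspot_peak(hd), c(12 + com[1] - com[1], -7), tolerance = 1,
               ignore_attr = TRUE)

  # two equal blobs: equal integrated mass within 2%, any bandwidth
  set.seed(97)
  P2 <- rbind(
    t(sapply(1:200, function(i) c(rnorm(2, c(-20, 0), 1.5), 0, 1, 0, 0, 0))),
    t(sapply(1:200, function(i) c(rnorm(2, c(20, 0), 1.5), 0, 1, 0, 0, 0))))
  for (bw in c(NULL, 1, 3)) {
    hd2 <- hotspot_density(traj_from_poses(P2), mob, selection = 1:20,
                           bandwidth = bw)
    left <- sum(hd2$density[hd2$x < 0, ]) * prod(hd2$cell)
    expect_equal(left, 0.5, tolerance = 0.02)
    expect_equal(glance(hd2)$integral, 1, tolerance = 1e-6)
  }
  expect_error(hotspot_density(traj_from_poses(P[1:5, ]), mob, 1:20),
               "at least 10")
})

test_that("phosphomimetic rescoring matches hand-computed Coulomb ratios", {
  # stationary: site atom at origin (q = 0) + far atom at (-8, 0, 0) (q = -1)
  sta <- bd_structure(tibble::tibble(
    serial = 1:2, name = c("OG", "CX"), element = c("O", "C"),
    resname = c("SER", "GLY"), resid = c(215L, 1L), chain = "A",
    x = c(0, -8), y = 0, z = 0, charge = c(0, -1),
    lj_rmin_half = 0, lj_epsilon = 0, vdw_radius = 1.5))
  mob <- point_structure(0, 0, 0, charge = 1)
  P <- matrix(rep(c(8, 0, 0, 1, 0, 0, 0), 4), ncol = 7, byrow = TRUE)
  tr <- traj_from_poses(P)
  clusters <- cluster_poses(tr, cbind(0, 0, 0), com = c(0, 0, 0))
  # identity modification: ratio exactly 1
  r_id <- phospho_rescore(tr, mob, sta, clusters, 215, c(OG = 0), cutoff = 20)
  expect_equal(r_id$ratio, 1.0)
  # 0 -> -2e at the site: ratio = (-1/16) / (-2/8 - 1/16) = 0.2
  r <- phospho_rescore(tr, mob, sta, clusters, 215, c(OG = -2), cutoff = 20)
  expect_equal(r$ratio, 0.2, tolerance = 1e-9)
  expect_equal(r$elec_original, 332.0636 * (-1 / 16), tolerance = 1e-9)
  # site beyond the cutoff in every frame: ratio 1
  r_far <- phospho_rescore(tr, mob, sta, clusters, 215, c(OG = -2),
                           cutoff = 6)
  expect_equal(r_far$ratio, 1.0)
  expect_error(phospho_rescore(tr, mob, sta, clusters, 999, c(OG = -2)),
               "not found")
})

test_that("tilt angles follow the axis orientation", {
  mob <- point_structure(c(0, 0), c(0, 0), c(0, 5), serial = 1:2)
  tr <- traj_from_poses(rbind(
    c(0, 0, 0, 1, 0, 0, 0),                               # axis along +z: 0
    c(0, 0, 0, quat_from_rotvec(c(0, pi / 2, 0))),        # rotated to x: 90
    c(0, 0, 0, quat_from_rotvec(c(0, pi / 4, 0)))))       # 45 degrees
  ta <- tilt_angle(tr, mob, 1, 2)
  expect_equal(ta$tilt_deg, c(0, 90, 45), tolerance = 1e-9)
  mob2 <- point_structure(c(0, 0), c(0, 0), c(1, 1), serial = 1:2)
  expect_error(tilt_angle(tr, mob2, 1, 2), "coincide")
})

test_that("membrane depth profiles report signed means and spreads", {
  mob <- point_structure(0, 0, 0)
  at_plane <- traj_from_poses(matrix(rep(c(0, 0, 5, 1, 0, 0, 0), 3),
                                     ncol = 7, byrow = TRUE))
  d <- membrane_depth_profile(at_plane, mob, list(R1 = 1), 5)
  expect_equal(d$mean_depth, 0)
  expect_equal(d$sd_depth, 0)

  below <- traj_from_poses(matrix(rep(c(0, 0, -5, 1, 0, 0, 0), 3),
                                  ncol = 7, byrow = TRUE))
  d2 <- membrane_depth_profile(below, mob, list(R1 = 1), 5)
  expect_equal(d2$mean_depth, -10)

  alt <- traj_from_poses(rbind(c(0, 0, -5, 1, 0, 0, 0),
                               c(0, 0, -15, 1, 0, 0, 0)))
  d3 <- membrane_depth_profile(alt, mob, list(R1 = 1), 0)
  expect_equal(d3$mean_depth, -10)
  expect_equal(d3$sd_depth, sd(c(-5, -15)))
  expect_error(membrane_depth_profile(alt, mob, list(R1 = integer()), 0),
               "empty selection")
})
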