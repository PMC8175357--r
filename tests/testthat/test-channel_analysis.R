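slab <- c(-20, 20)

test_that("crossing counter requires complete passes", {
  expect_equal(count_crossings(seq(-40, 40, by = 5), slab)[, c("n_up", "n_down")],
               tibble::tibble(n_up = 1L, n_down = 0L))
  # enters and returns: no crossing
  expect_equal(count_crossings(c(-40, -10, 0, -10, -40), slab)$n_up, 0L)
  expect_equal(count_crossings(c(-40, -10, 0, -10, -40), slab)$n_down, 0L)
  # alternating passes: up 3, down 2, net 1 (hand-traced state machine)
  z <- c(-40, 0, 40, 0, -40, 0, 40, 10, -5, -40, -10, 5, 40)
  cc <- count_crossings(z, slab)
  expect_equal(cc$n_up, 3L)
  expect_equal(cc$n_down, 2L)
  expect_error(count_crossings(c(-40, NaN, 40), slab), "non-finite")
})

test_that("crossing counting is time-reversal antisymmetric", {
  set.seed(101)
  for (i in 1:20) {
    z <- cumsum(rnorm(300, mean = runif(1, -2, 2), sd = 8)) - 30
    fwd <- count_crossings(z, slab)
    rev_ <- count_crossings(rev(z), slab)
    expect_equal(fwd$n_up, rev_$n_down)
    expect_equal(fwd$n_down, rev_$n_up)
  }
})

test_that("scheduled tracks reproduce generator ground truth exactly", {
  set.seed(102)
  for (rep in 1:20) {
    schedule <- tibble::tibble(
      species = sample(c("Na+", "Cl-"), 6, replace = TRUE),
      n_down = sample(0:3, 6, replace = TRUE),
      n_up = pmax(0, n_down + sample(-1:1, 6, replace = TRUE)),
      n_feints = sample(0:3, 6, replace = TRUE))
    tr <- make_ion_tracks(schedule, slab = slab, noise = 2, seed = 200 + rep)
    got <- count_crossings(tr)
    expect_equal(got$n_up, schedule$n_up)
    expect_equal(got$n_down, schedule$n_down)
  }
  # noiseless tracks realise the waypoints exactly
  tr0 <- make_ion_tracks(tibble::tibble(species = "Cl-", n_up = 5, n_down = 4,
                                        n_feints = 2), slab = slab, noise = 0)
  expect_equal(count_crossings(tr0)$n_up, 5L)
  expect_equal(max(tr0$z), 30)
  # feints only
  trf <- make_ion_tracks(tibble::tibble(species = "Na+", n_up = 0, n_down = 0,
                                        n_feints = 3), slab = slab)
  expect_equal(unlist(count_crossings(trf)[, c("n_up", "n_down")]),
               c(n_up = 0L, n_down = 0L))
})

test_that("currents follow I = N q / tau with signed species charges", {
  one_na <- tibble::tibble(species = "Na+", n_up = 1, n_down = 0)
  cr <- compute_current(one_na, tau_s = 1e-9)
  expect_equal(cr$total_A, 1.60217662e-10, tolerance = 1e-12)
  expect_equal(cr$total_A * 1e9, 0.160, tolerance = 1e-2)    # 0.160 nA

  both_up <- tibble::tibble(species = c("Na+", "Cl-"), n_up = 1, n_down = 0)
  expect_equal(compute_current(both_up, 1e-9)$total_A, 0)

  cl_down <- tibble::tibble(species = "Cl-", n_up = 0, n_down = 1)
  expect_equal(compute_current(cl_down, 1e-9)$total_A,
               compute_current(one_na, 1e-9)$total_A, tolerance = 1e-15)

  # linear in counts, inverse-linear in tau
  many <- tibble::tibble(species = "Na+", n_up = 7, n_down = 0)
  expect_equal(compute_current(many, 1e-9)$total_A, 7 * cr$total_A)
  expect_equal(compute_current(one_na, 2e-9)$total_A, cr$total_A / 2)
  expect_error(compute_current(one_na, 0), "positive")
})

test_that("cumulative crossing events carry times and directions", {
  tr <- make_ion_tracks(tibble::tibble(species = c("Na+", "Cl-"),
                                       n_up = c(2, 1), n_down = c(1, 0),
                                       n_feints = 0), slab = slab)
  res <- ionic_current(tr)
  ev <- res$events
  expect_equal(sum(ev$direction[ev$species == "Na+"]), 1)
  expect_equal(sum(ev$direction[ev$species == "Cl-"]), 1)
  expect_true(all(diff(ev$time_ns) >= 0))
  expect_s3_class(glance(res), "tbl_df")
})

test_that("pore profile recovers cylinder, cap, and waist geometry", {
  cyl <- make_cylinder_pore(R = 12, atom_vdw = 1.7, z_height = 30)
  pp <- pore_profile(cyl, z_range = c(-12, 12), z_step = 1)
  interior <- pp[!pp$bulk, ]
  expect_true(all(abs(interior$radius - 10.3) <= 0.2))

  # hourglass of two cones: waist within one z-step of the truth
  zs <- seq(-15, 15, by = 1)
  rows <- do.call(rbind, lapply(zs, function(z) {
    r <- 4 + 8 * abs(z) / 15
    n <- max(8, ceiling(2 * pi * r))
    a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(r * cos(a), r * sin(a), z)
  }))
  hg <- point_structure(rows[, 1], rows[, 2], rows[, 3], vdw = 1.7,
                        serial = seq_len(nrow(rows)))
  ph <- pore_profile(hg, z_range = c(-12, 12), z_step = 1)
  g <- glance(ph)
  expect_lte(abs(g$waist_z - 0), 1)
  expect_equal(g$min_radius, 4 - 1.7, tolerance = 0.2)

  # empty slice: clamp + flag
  pe <- pore_profile(cyl, z_range = c(40, 42), z_step = 1, clamp = 15)
  expect_true(all(pe$bulk))
  expect_true(all(pe$radius == 15))
})

test_that("pore profile is invariant to rotation about the axis", {
  cyl <- make_cylinder_pore(R = 12, z_height = 30)
  pp <- pore_profile(cyl, z_range = c(-12, 12), z_step = 1)
  R <- quat_to_matrix(quat_from_rotvec(c(0, 0, 0.7)))
  Xr <- cbind(cyl$x, cyl$y, cyl$z) %*% t(R)
  cyl2 <- cyl
  cyl2$x <- Xr[, 1]; cyl2$y <- Xr[, 2]; cyl2$z <- Xr[, 3]
  pp2 <- pore_profile(cyl2, z_range = c(-12, 12), z_step = 1)
  expect_lte(max(abs(pp$radius - pp2$radius)), 0.05)
})

test_that("hydrogen bonds require both distance and angle criteria", {
  # collinear D-H...A at D-A = 2.8: reported with angle 180
  s <- point_structure(c(0, 1, 2.8), c(0, 0, 0), c(0, 0, 0),
                       element = c("O", "H", "O"), serial = 1:3)
  hb <- hydrogen_bonds(s, donors = 1, hydrogens = 2, acceptors = 3)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$angle_DHA, 180, tolerance = 1e-6)
  expect_equal(hb$distance_DA, 2.8)

  # D-A = 3.2: rejected regardless of angle
  s2 <- point_structure(c(0, 1, 3.2), c(0, 0, 0), c(0, 0, 0),
                        element = c("O", "H", "O"), serial = 1:3)
  expect_equal(nrow(hydrogen_bonds(s2, 1, 2, 3)), 0)

  # D-A = 2.8 but D-H-A = 100 degrees (law of cosines): rejected
  t_len <- cos(100 * pi / 180) + sqrt(cos(100 * pi / 180)^2 + 2.8^2 - 1)
  A <- c(1, 0, 0) + t_len * c(cos(80 * pi / 180), sin(80 * pi / 180), 0)
  s3 <- point_structure(c(0, 1, A[1]), c(0, 0, A[2]), c(0, 0, A[3]),
                        element = c("O", "H", "O"), serial = 1:3)
  expect_equal(sqrt(sum(A^2)), 2.8, tolerance = 1e-9)  # construction check
  expect_equal(nrow(hydrogen_bonds(s3, 1, 2, 3)), 0)

  # missing hydrogen: donor skipped with a warning
  expect_warning(hb4 <- hydrogen_bonds(s, donors = c(1, 3),
                                       hydrogens = c(2, NA), acceptors = 3),
                 "without a bound hydrogen")
  expect_equal(nrow(hb4), 1)
})
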