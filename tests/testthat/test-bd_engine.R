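test_that("Stokes-Einstein diffusion obeys the scaling laws", {
  m <- stokes_diffusion(20, 0.6913, 310)
  expect_equal(m$d_trans, 16.4, tolerance = 0.01)
  m2 <- stokes_diffusion(40, 0.6913, 310)
  expect_equal(m2$d_trans, m$d_trans / 2, tolerance = 1e-10)
  expect_equal(m2$d_rot, m$d_rot / 8, tolerance = 1e-10)
  m3 <- stokes_diffusion(20, 0.6913, 620)
  expect_equal(m3$d_trans, 2 * m$d_trans, tolerance = 1e-10)
  expect_equal(m3$d_rot, 2 * m$d_rot, tolerance = 1e-10)
  expect_error(stokes_diffusion(-1, 1, 310), "positive")
})

test_that("grid force/torque: uniform field and dipole limits", {
  # single +1e cell in V = -E z (E = 1): force (0, 0, 1), zero torque
  frame <- list(origin = c(-5, -5, -5), spacing = c(1, 1, 1),
                dim = c(11L, 11L, 11L))
  ax <- seq(-5, 5)
  vals <- array(0, dim = c(11, 11, 11))
  for (k in 1:11) vals[, , k] <- -ax[k]
  zero_lj <- grid_map(array(0, dim = c(11, 11, 11)), origin = frame$origin)
  maps <- structure(list(
    elec = grid_map(vals, origin = frame$origin),
    lj = list(CS = zero_lj), provenance = "internal-screened-coulomb",
    frame = frame, categories = NULL), class = "map_set")
  s <- point_structure(0, 0, 0, charge = 1)
  dens <- build_density_set(s, spacing = 1, margin = 2)
  ft <- grid_force_torque(dens, maps, c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(ft$force, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(ft$torque, c(0, 0, 0), tolerance = 1e-12)

  # +/- 1e cells 2 A apart along x: zero net force, torque 2 about y-hat
  s2 <- point_structure(c(1, -1), c(0, 0), c(0, 0), charge = c(1, -1),
                        serial = 1:2)
  dens2 <- build_density_set(s2, spacing = 1, margin = 2)
  ft2 <- grid_force_torque(dens2, maps, c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(ft2$force, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ft2$torque, c(0, -2, 0), tolerance = 1e-12)
})

test_that("grid force is the exact negative gradient of the interpolated energy", {
  sta <- make_random_body(15, 6, seed = 51)
  mob <- make_random_body(8, 3, seed = 52)
  frame <- list(origin = c(-25, -25, -25), spacing = c(1, 1, 1),
                dim = c(51L, 51L, 51L))
  maps <- build_map_set(sta, frame = frame, cutoff = 34, cap = 30,
                        solvent_dielectric = 78)
  dens <- build_density_set(mob)
  com <- dens$com
  energy_of <- function(pose) {
    tot <- interp_density <- 0
    cells <- function(g) {
      idx <- which(g$values != 0, arr.ind = TRUE)
      pos <- cbind(g$origin[1] + (idx[, 1] - 1) * g$spacing[1] - com[1],
                   g$origin[2] + (idx[, 2] - 1) * g$spacing[2] - com[2],
                   g$origin[3] + (idx[, 3] - 1) * g$spacing[3] - com[3])
      list(pos = pos, w = g$values[idx])
    }
    add <- function(map, grid) {
      cl <- cells(grid)
      pts <- sweep(cl$pos %*% t(quat_to_matrix(pose[4:7])), 2, pose[1:3], "+")
      sum(cl$w * interpolate(map, pts))
    }
    tot <- add(maps$elec, dens$charge)
    for (lab in names(dens$lj)) tot <- tot + add(maps$lj[[lab]], dens$lj[[lab]])
    tot
  }
  set.seed(53)
  h <- 1e-6
  for (i in 1:10) {
    d <- runif(1, 12, 16) * {v <- rnorm(3); v / sqrt(sum(v^2))}
    pose <- c(d, quat_random())
    ft <- grid_force_torque(dens, maps, pose)
    num <- sapply(1:3, function(ax) {
      pp <- pm <- pose
      pp[ax] <- pp[ax] + h; pm[ax] <- pm[ax] - h
      -(energy_of(pp) - energy_of(pm)) / (2 * h)
    })
    expect_equal(ft$force, num, tolerance = 1e-4)
  }
})

test_that("bd_step drifts deterministically without noise", {
  model <- diffusion_model(50, 0.1, 310)
  st <- list(t = c(0, 0, 0), q = c(1, 0, 0, 0))
  st1 <- bd_step(st, c(0, 0, 0), c(0, 0, 0), model, 2e-4, noise = FALSE)
  expect_equal(st1$t, c(0, 0, 0))
  expect_equal(st1$q, c(1, 0, 0, 0))
  st2 <- bd_step(st, c(0, 0, 3), c(0, 0, 0), model, 2e-4, noise = FALSE)
  expect_equal(st2$t[3], 50 * 3 * 2e-4 / kT(310), tolerance = 1e-12)
})

test_that("run_bd is stationary with zero fields and noise off", {
  model <- diffusion_model(100, 0.1, 310)
  params <- bd_params(duration_ns = 1, output_stride_ns = 0.2, seed = 61)
  traj <- run_bd(NULL, NULL, model, params,
                 matrix(c(1, 2, 3, 1, 0, 0, 0), nrow = 1), noise = FALSE)
  expect_true(all(traj$x == 1 & traj$y == 2 & traj$z == 3))
  expect_true(all(traj$qw == 1))
})

test_that("run_bd is bit-reproducible per seed and diverges across seeds", {
  model <- diffusion_model(100, 0.1, 310)
  p1 <- bd_params(duration_ns = 0.5, output_stride_ns = 0.1, seed = 71)
  init <- matrix(c(0, 0, 0, 1, 0, 0, 0), nrow = 1)
  a <- run_bd(NULL, NULL, model, p1, init)
  b <- run_bd(NULL, NULL, model, p1, init)
  expect_identical(as.data.frame(a), as.data.frame(b))
  p2 <- bd_params(duration_ns = 0.5, output_stride_ns = 0.1, seed = 72)
  c2 <- run_bd(NULL, NULL, model, p2, init)
  expect_false(isTRUE(all.equal(a$x, c2$x)))
  expect_equal(attr(a, "seed"), 71L)
})

test_that("run_bd writes files that round trip with the header intact", {
  model <- diffusion_model(100, 0.1, 310)
  params <- bd_params(duration_ns = 0.5, output_stride_ns = 0.1, seed = 73)
  traj <- run_bd(NULL, NULL, model, params, matrix(c(0, 0, 0, 1, 0, 0, 0), 1))
  f <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(back$x, traj$x, tolerance = 1e-10)
})

test_that("run_bd rejects an initial pose overlapping the stationary body", {
  sta <- make_toy_barrel()
  mob <- make_anchor_probe()
  frame <- grid_frame(sta, margin = 10)
  maps <- suppressWarnings(build_map_set(sta, frame = frame))
  dens <- build_density_set(mob)
  model <- diffusion_model(30, 0.1, 310)
  params <- bd_params(duration_ns = 0.2, seed = 74)
  # probe COM placed inside the barrel wall lattice
  bad <- matrix(c(15, 0, 0, 1, 0, 0, 0), nrow = 1)
  expect_error(run_bd(dens, maps, model, params, bad, restraints = NULL),
               "overlaps")
})

test_that("equilibrium in a harmonic z-well matches Boltzmann statistics", {
  kc <- 0.5
  zg <- seq(-12, 12, by = 0.25)
  pot <- structure(tibble::tibble(z = zg, U = 0.5 * kc * zg^2),
                   class = c("z_potential", class(tibble::tibble())))
  rs <- restraint_set(list(A = pot), wall_radius = Inf)
  model <- diffusion_model(100, 0.1, 310)
  params <- bd_params(duration_ns = 100, output_stride_ns = 0.02, seed = 81)
  traj <- run_bd(NULL, NULL, model, params, matrix(c(0, 0, 0, 1, 0, 0, 0), 1),
                 restraints = rs,
                 anchors = tibble::tibble(label = "A", x = 0, y = 0, z = 0))
  zs <- traj$z[traj$time_ns > 5]
  expect_equal(var(zs), kT(310) / kc, tolerance = 0.1)
  # one-sample KS against the Boltzmann marginal on decorrelated samples
  thin <- zs[seq(1, length(zs), by = 3)]
  ks <- suppressWarnings(stats::ks.test(thin, "pnorm", 0, sqrt(kT(310) / kc)))
  expect_gt(ks$p.value, 0.01)
})
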