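test_that("LJ category collapsing averages Rmin and scales epsilon", {
  s <- point_structure(x = c(0, 1, 2), y = 0 * 1:3, z = 0 * 1:3,
                       charge = 0, rmin_half = 2.0, eps = 0.1)
  cats <- suppressWarnings(collapse_lj_categories(s))
  cs <- cats[cats$label == "CS", ]
  expect_equal(cs$rmin_mean, 4.0)           # Rmin = 2 * Rmin/2
  expect_equal(cs$eps_scaled, 0.03)         # 0.1 * 0.3
  expect_equal(cats$n_atoms[cats$label == "H"], 0)

  # mixed O/N category: mean(0.12, 0.20, 0.20) * 0.3 = 0.052
  s2 <- bd_structure(tibble::tibble(
    serial = 1:3, name = c("O1", "O2", "N1"), element = c("O", "O", "N"),
    resname = "X", resid = 1:3, chain = "A",
    x = c(0, 1, 2), y = 0, z = 0, charge = 0,
    lj_rmin_half = 1.7, lj_epsilon = c(0.12, 0.20, 0.20), vdw_radius = 1.5))
  cats2 <- suppressWarnings(collapse_lj_categories(s2))
  expect_equal(cats2$eps_scaled[cats2$label == "ON"], 0.052)

  # scale 1 reproduces the unscaled mean
  cats3 <- suppressWarnings(collapse_lj_categories(s2, scale = 1))
  expect_equal(cats3$eps_scaled[cats3$label == "ON"], mean(c(0.12, 0.2, 0.2)))

  s2$element[1] <- "P"
  expect_error(collapse_lj_categories(s2), "not one of H, O, N, C, S")
})

test_that("cloud-in-cell deposition spreads trilinear weights and conserves totals", {
  frame <- list(origin = c(0, 0, 0), spacing = c(1, 1, 1), dim = c(5L, 5L, 5L))
  # atom exactly on a node: all weight in that cell
  s <- point_structure(2, 3, 1, charge = 1)
  d <- deposit_density(s, "charge", frame)
  expect_equal(d$values[3, 4, 2], 1)
  expect_equal(sum(d$values != 0), 1)

  # atom at a cell centre: eight nodes at 0.125 each
  s <- point_structure(1.5, 1.5, 1.5, charge = 1)
  d <- deposit_density(s, "charge", frame)
  expect_equal(sort(d$values[d$values != 0]), rep(0.125, 8))

  # conservation for an arbitrary seeded body
  body <- make_random_body(50, 8, seed = 21)
  frame <- grid_frame(body, margin = 2)
  d <- deposit_density(body, "charge", frame)
  expect_equal(sum(d$values), total_charge(body), tolerance = 1e-12)
  for (lab in c("H", "ON", "CS")) {
    dc <- deposit_density(body, lab, frame)
    n_lab <- sum(c(H = "H", O = "ON", N = "ON", C = "CS", S = "CS")[
      body$element] == lab)
    expect_equal(sum(dc$values), n_lab, tolerance = 1e-12)
  }

  # atom outside the grid names its serial
  s <- point_structure(99, 0, 0, charge = 1, serial = 7L)
  expect_error(deposit_density(s, "charge",
                               list(origin = c(0, 0, 0), spacing = c(1, 1, 1),
                                    dim = c(4L, 4L, 4L))), "serial 7")
})

test_that("screened Coulomb map reproduces Coulomb's law and Debye screening", {
  s <- point_structure(0, 0, 0, charge = 1)
  frame <- list(origin = c(-12, -12, -12), spacing = c(1, 1, 1),
                dim = c(25L, 25L, 25L))
  m <- screened_coulomb_map(s, frame, solvent_dielectric = 1,
                            ionic_strength = 0, cutoff = 34, cap = 1000)
  expect_equal(interpolate(m, c(10, 0, 0)), 33.20636, tolerance = 1e-6)
  expect_equal(attr(m, "provenance"), "internal-screened-coulomb")

  # zero charges give the zero map
  s0 <- point_structure(0, 0, 0, charge = 0)
  m0 <- screened_coulomb_map(s0, frame)
  expect_true(all(m0$values == 0))

  # Debye screening: V_I / V_0 = exp(-r / 7.85) at I = 0.15 M
  ms <- screened_coulomb_map(s, frame, solvent_dielectric = 1,
                             ionic_strength = 0.15, cutoff = 34, cap = 1000)
  r <- 7.85
  ratio <- interpolate(ms, c(r, 0, 0)) / interpolate(m, c(r, 0, 0))
  expect_equal(ratio, exp(-r / (3.04 / sqrt(0.15))), tolerance = 0.01)

  expect_error(screened_coulomb_map(s, frame, ionic_strength = -1), ">= 0")
  expect_error(screened_coulomb_map(s, frame, cutoff = 0), "positive")
})

test_that("Coulomb map matches a direct pairwise oracle beyond the clamp zone", {
  body <- make_random_body(15, 6, seed = 31)
  frame <- list(origin = c(-15, -15, -15), spacing = c(1.5, 1.5, 1.5),
                dim = c(21L, 21L, 21L))
  m <- screened_coulomb_map(body, frame, solvent_dielectric = 78,
                            ionic_strength = 0, cutoff = 60, cap = 1e6)
  ax <- grid_axes(m)
  nodes <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  X <- cbind(body$x, body$y, body$z)
  d2 <- outer(rowSums(nodes^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(nodes)), rowSums(X^2)) - 2 * nodes %*% t(X)
  d <- sqrt(pmax(d2, 0))
  oracle <- (1 / d) %*% body$charge * 332.0636 / 78
  far <- apply(d, 1, min) > 1.5
  got <- as.numeric(m$values)[far]
  expect_equal(got, oracle[far], tolerance = 1e-6)
  expect_true(all(is.finite(m$values)))
})

test_that("LJ potential map has the pair minimum, decays, and adds pairwise", {
  cat1 <- tibble::tibble(label = "CS", n_atoms = 1, rmin_mean = 4.0,
                         eps_scaled = 0.06)
  s <- point_structure(0, 0, 0, rmin_half = 2.0, eps = 0.15)
  rij <- 2.0 + 4.0 / 2        # 4 A
  eij <- sqrt(0.15 * 0.06)
  frame <- list(origin = c(-16, -16, -16), spacing = c(0.5, 0.5, 0.5),
                dim = c(65L, 65L, 65L))
  m <- lj_potential_map(s, cat1, frame, cutoff = 34, cap = 30)
  expect_equal(interpolate(m, c(rij, 0, 0)), -eij, tolerance = 1e-9)
  expect_lt(abs(interpolate(m, c(15.9, 0, 0))), 1e-3)

  # two symmetric atoms double the single-atom value at the midpoint plane
  s2 <- point_structure(c(-5, 5), c(0, 0), c(0, 0), rmin_half = 2.0,
                        eps = 0.15, serial = 1:2)
  m2 <- lj_potential_map(s2, cat1, frame, cutoff = 34, cap = 30)
  u_single <- eij * ((rij / 5)^12 - 2 * (rij / 5)^6)
  expect_equal(interpolate(m2, c(0, 0, 0)), 2 * u_single, tolerance = 1e-6)

  # clamped, finite everywhere (node on the atom centre included)
  expect_true(all(is.finite(m$values)))
  expect_lte(max(m$values), 30)
  expect_error(lj_potential_map(s, cat1, frame, cap = -1), "positive")
})

test_that("trilinear interpolation reproduces linear fields and node values", {
  ax <- list(x = 0:6, y = 0:5, z = 0:7)
  vals <- array(0, dim = c(7, 6, 8))
  for (k in 1:8) vals[, , k] <- 2 * ax$z[k]
  g <- grid_map(vals, origin = c(0, 0, 0))
  set.seed(41)
  pts <- cbind(runif(20, 0, 6), runif(20, 0, 5), runif(20, 0, 7))
  expect_equal(interpolate(g, pts), 2 * pts[, 3], tolerance = 1e-12)
  gr <- gradient(g, pts)
  expect_equal(gr, cbind(0 * pts[, 1], 0, 2), ignore_attr = TRUE,
               tolerance = 1e-12)
  # node value equals stored value
  set.seed(42)
  g2 <- grid_map(array(rnorm(7 * 6 * 8), dim = c(7, 6, 8)), origin = c(0, 0, 0))
  expect_equal(interpolate(g2, c(3, 2, 5)), g2$values[4, 3, 6])
})

test_that("analytic gradient matches central differences at interior points", {
  set.seed(43)
  g <- grid_map(array(rnorm(20^3), dim = c(20, 20, 20)), origin = c(0, 0, 0))
  pts <- cbind(runif(100, 2, 17), runif(100, 2, 17), runif(100, 2, 17))
  # keep away from cell faces where the interpolant's gradient jumps
  pts <- pts - (pts - floor(pts) - 0.5) * 0.02
  ana <- gradient(g, pts)
  h <- 1e-6
  for (d in 1:3) {
    hp <- hm <- pts
    hp[, d] <- hp[, d] + h; hm[, d] <- hm[, d] - h
    num <- (interpolate(g, hp) - interpolate(g, hm)) / (2 * h)
    expect_equal(ana[, d], num, tolerance = 1e-6)
  }
})

test_that("out-of-bounds policies behave as declared", {
  g <- grid_map(array(1, dim = c(3, 3, 3)), origin = c(0, 0, 0),
                out_of_bounds = "zero")
  expect_equal(interpolate(g, c(10, 0, 0)), 0)
  g$out_of_bounds <- "clamp"
  expect_equal(interpolate(g, c(10, 0, 0)), 1)
  g$out_of_bounds <- "error"
  expect_error(interpolate(g, c(10, 0, 0)), "outside")
})
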