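# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn cluster_poses Tidy cluster summary (one row per cluster,
#'   without the list column).
#' @param x A `pose_clusters` object.
#' @param ... Unused.
#' @method tidy pose_clusters
#' @export
tidy.pose_clusters <- function(x, ...) {
  out <- as_tibble(x)
  out$frames <- NULL
  out
}

#' @describeIn cluster_poses One-row clustering summary.
#' @method glance pose_clusters
#' @export
glance.pose_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_frames = sum(x$n),
         top_population = if (nrow(x)) x$population[1] else NA_real_)
}

#' @describeIn compute_current Per-species crossing counts and currents.
#' @param x A `current_result`.
#' @param ... Unused.
#' @method tidy current_result
#' @export
tidy.current_result <- function(x, ...) x$per_species

#' @describeIn compute_current One-row total current summary.
#' @method glance current_result
#' @export
glance.current_result <- function(x, ...) {
  tibble(total_A = x$total_A, total_pA = x$total_A * 1e12, tau_s = x$tau_s)
}

#' @describeIn hotspot_density Long-format density table (`x`, `y`,
#'   `density`).
#' @param x A `hotspot_density`.
#' @param ... Unused.
#' @method tidy hotspot_density
#' @export
tidy.hotspot_density <- function(x, ...) {
  xs <- rep(x$x, times = length(x$y))
  ys <- rep(x$y, each = length(x$x))
  dens <- as.numeric(x$density)
  tibble(x = xs, y = ys, density = dens)
}

#' @describeIn hotspot_density One-row summary (peak location, integral).
#' @method glance hotspot_density
#' @export
glance.hotspot_density <- function(x, ...) {
  pk <- hotspot_peak(x)
  tibble(peak_x = pk[1], peak_y = pk[2],
         integral = sum(x$density) * prod(x$cell),
         bandwidth_x = x$bandwidth[1], bandwidth_y = x$bandwidth[2])
}

#' @describeIn pore_profile One-row summary: the constriction (waist).
#' @param x A `pore_profile`.
#' @param ... Unused.
#' @method glance pore_profile
#' @export
glance.pore_profile <- function(x, ...) {
  interior <- x[!x$bulk, ]
  if (nrow(interior) == 0) interior <- x
  i <- which.min(interior$radius)
  tibble(min_radius = interior$radius[i], waist_z = interior$z[i],
         n_slices = nrow(x))
}

#' Quadratic curvature of a 1-D potential about its minimum
#'
#' Fits `U = a + b z + (k/2) z^2` over bins within `window` of the minimum
#' and returns `k` -- for a Boltzmann-inverted Gaussian of width sigma this
#' recovers `k_B T / sigma^2`.
#'
#' @param potential A `z_potential` (tibble with `z`, `U`).
#' @param window Half-width of the fit window (Angstrom, default 2).
#' @return Curvature `k` in kcal/mol/A^2.
#' @export
potential_curvature <- function(potential, window = 2) {
  z0 <- potential$z[which.min(potential$U)]
  sel <- abs(potential$z - z0) <= window
  if (sum(sel) < 3) abort("too few bins in the fit window")
  fit <- lm(U ~ z + I(z^2), data = potential[sel, ])
  2 * coef(fit)[["I(z^2)"]]
}
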