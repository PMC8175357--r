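# Membrane anchoring: 1-D z potentials obtained by Boltzmann inversion of
# observed z distributions of anchor residues, applied to each residue's COM
# during BD, plus a flat-bottomed circular wall confining lateral diffusion.

#' Boltzmann inversion of a 1-D coordinate distribution
#'
#' Turns z samples of a membrane-anchored residue into a grid potential
#' `U(z) = -k_B T log p(z)`, with `p` estimated by a histogram. Empty bins
#' strictly inside the sampled support receive `pseudocount` counts so the
#' potential stays finite there; `U` is shifted so its minimum is zero.
#' Outside the support the potential continues with the linear slope of the
#' edge bins (applied by the BD engine), keeping anchors confined without
#' infinite walls.
#'
#' @param z Numeric vector of z samples (Angstrom), at least 100.
#' @param temperature Temperature in Kelvin.
#' @param bin_width Histogram bin width in Angstrom (default 0.5).
#' @param pseudocount Count added to empty interior bins (default 1).
#' @param label Optional residue label (e.g. `"M1"`).
#' @return A `z_potential`: tibble with columns `z` (bin centres) and `U`
#'   (kcal/mol), with `temperature`, `bin_width` and `label` attributes.
#' @export
boltzmann_invert <- function(z, temperature, bin_width = 0.5, pseudocount = 1,
                             label = "") {
  if (temperature <= 0) abort("temperature must be positive")
  if (bin_width <= 0) abort("bin_width must be positive")
  if (!all(is.finite(z))) abort("z samples must be finite")
  if (length(z) < 100) abort("Boltzmann inversion needs at least 100 samples")
  if (diff(range(z)) < .Machine$double.eps * 100)
    abort("all samples identical: zero-width distribution cannot be inverted")
  lo <- floor(min(z) / bin_width) * bin_width
  hi <- ceiling(max(z) / bin_width) * bin_width
  if (hi - lo < 2 * bin_width) hi <- lo + 2 * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  counts <- as.numeric(table(cut(z, breaks = breaks, include.lowest = TRUE)))
  nz <- which(counts > 0)
  counts <- counts[nz[1]:nz[length(nz)]]
  counts[counts == 0] <- pseudocount
  centres <- (breaks[-length(breaks)] + bin_width / 2)[nz[1]:nz[length(nz)]]
  p <- counts / sum(counts)
  U <- -kT(temperature) * log(p)
  U <- U - min(U)
  structure(tibble(z = centres, U = U),
            class = c("z_potential", class(tibble())),
            temperature = temperature, bin_width = bin_width, label = label)
}

#' Confinement-wall force
#'
#' Zero inside the wall radius; an inward harmonic restoring force
#' `stiffness * (r - wall_radius)` beyond it, acting on the lateral (x, y)
#' position. Continuous at the wall.
#'
#' @param position Numeric length-2 or length-3 position (Angstrom).
#' @param wall_radius Wall radius in Angstrom (default 150).
#' @param stiffness Force constant, kcal/mol/A^2 (default 10).
#' @param center Lateral centre of the wall (default origin).
#' @return Length-3 force vector in kcal/mol/A (z component zero).
#' @export
wall_force <- function(position, wall_radius = 150, stiffness = 10,
                       center = c(0, 0)) {
  if (stiffness < 0) abort("stiffness must be >= 0")
  d <- position[1:2] - center
  r <- sqrt(sum(d^2))
  if (r <= wall_radius || r == 0) return(c(0, 0, 0))
  f <- -stiffness * (r - wall_radius) * d / r
  c(f, 0)
}

#' z-shift aligning two membrane midplanes
#'
#' @param mobile_midplane_z,stationary_midplane_z Midplane z of each body
#'   (Angstrom).
#' @return The shift to add to the mobile body's z so the midplanes match.
#' @export
align_membrane_frames <- function(mobile_midplane_z, stationary_midplane_z) {
  if (!is.finite(mobile_midplane_z) || !is.finite(stationary_midplane_z))
    abort("midplane positions must be finite")
  stationary_midplane_z - mobile_midplane_z
}

#' Bundle per-residue z potentials and the wall into a restraint set
#'
#' @param potentials Named list of [boltzmann_invert()] outputs, keyed by
#'   anchor residue label.
#' @param wall_radius Wall radius (Angstrom), default 150.
#' @param wall_stiffness Wall force constant (kcal/mol/A^2), default 10.
#' @param wall_center Lateral wall centre.
#' @return A `restraint_set` object.
#' @export
restraint_set <- function(potentials = list(), wall_radius = 150,
                          wall_stiffness = 10, wall_center = c(0, 0)) {
  stopifnot(is.list(potentials))
  structure(list(potentials = potentials, wall_radius = wall_radius,
                 wall_stiffness = wall_stiffness, wall_center = wall_center),
            class = "restraint_set")
}

#' Derive a restraint set from a residue-labelled z-sample table
#'
#' @param samples A data frame with columns `residue_label` and `z`.
#' @param temperature Temperature in Kelvin.
#' @param ... Passed to [boltzmann_invert()].
#' @inheritParams restraint_set
#' @return A [restraint_set()].
#' @export
derive_restraints <- function(samples, temperature, ...,
                              wall_radius = 150, wall_stiffness = 10,
                              wall_center = c(0, 0)) {
  labs <- unique(samples$residue_label)
  pots <- lapply(labs, function(l)
    boltzmann_invert(samples$z[samples$residue_label == l], temperature,
                     label = l, ...))
  names(pots) <- labs
  restraint_set(pots, wall_radius, wall_stiffness, wall_center)
}

#' Sample a 1-D grid potential with overdamped Brownian dynamics
#'
#' Propagates a single coordinate in the linearly interpolated potential
#' (the same force rule the rigid-body engine applies to anchors) and
#' returns thinned samples. Randomness comes from R's RNG; call `set.seed()`
#' for reproducibility.
#'
#' @param potential A `z_potential` from [boltzmann_invert()], or any tibble
#'   with equally spaced `z` and `U` columns.
#' @param temperature Temperature in Kelvin.
#' @param d_trans Diffusion coefficient, A^2/ns (default 100).
#' @param dt Timestep in ns (default 1e-4).
#' @param n_steps Number of steps.
#' @param stride Keep every `stride`-th sample.
#' @param burn_in Steps discarded before recording starts.
#' @param z_init Initial coordinate; defaults to the potential minimum.
#' @return Numeric vector of z samples.
#' @export
sample_z_potential <- function(potential, temperature, d_trans = 100,
                               dt = 1e-4, n_steps = 1e6, stride = 10,
                               burn_in = 1e4, z_init = NULL) {
  dz <- unique(round(diff(potential$z), 10))
  if (length(dz) != 1) abort("potential grid must be equally spaced")
  if (is.null(z_init)) z_init <- potential$z[which.min(potential$U)]
  all_steps <- as.integer(burn_in + n_steps)
  out <- cpp_sample_1d(potential$z[1], dz, potential$U, d_trans,
                       kT(temperature), dt, all_steps, as.integer(stride),
                       z_init)
  out[-seq_len(ceiling(burn_in / stride))]
}

#' Write / read a two-column z-potential file
#'
#' @param potential A `z_potential`.
#' @param path File path.
#' @return `path` (writer) or a `z_potential` (reader).
#' @export
write_z_potential <- function(potential, path) {
  writeLines(c(paste0("# label: ", attr(potential, "label") %||% ""),
               paste0("# temperature_K: ", attr(potential, "temperature")),
               "z U",
               sprintf("%.10g %.10g", potential$z, potential$U)), path)
  invisible(path)
}

#' @rdname write_z_potential
#' @export
read_z_potential <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  getv <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit)) trimws(sub(".*:", "", hit[1])) else default
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  structure(as_tibble(df), class = c("z_potential", class(tibble())),
            temperature = as.numeric(getv("temperature_K", NA)),
            bin_width = round(diff(df$z[1:2]), 10),
            label = getv("label", ""))
}
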