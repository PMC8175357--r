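# The BD force field: the stationary body becomes potential maps (one
# electrostatic, one LJ map per collapsed atom category); the mobile body
# becomes matching density grids (charge and per-category particle counts).

CATEGORY_LABELS <- c("H", "ON", "CS")

element_category <- function(element, serial = NULL) {
  out <- dplyr::case_when(
    element == "H" ~ "H",
    element %in% c("O", "N") ~ "ON",
    element %in% c("C", "S") ~ "CS",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    abort(paste0("element '", element[i], "' of atom",
                 if (!is.null(serial)) paste0(" serial ", serial[i]),
                 " is not one of H, O, N, C, S"))
  }
  out
}

#' Collapse per-atom LJ parameters into three element categories
#'
#' All atoms are partitioned into hydrogens (`H`), oxygens + nitrogens
#' (`ON`), and carbons + sulfurs (`CS`). Each category carries the
#' arithmetic mean of its members' Rmin (full minimum-energy distance,
#' i.e. `2 * lj_rmin_half`) and the mean well depth scaled by `scale`
#' (default 0.3, which damps protein stickiness in the rigid-body model).
#'
#' @param structure A [bd_structure()] with LJ parameters populated.
#' @param scale Multiplier applied to the mean well depth.
#' @return A tibble with columns `label`, `n_atoms`, `rmin_mean` (Angstrom),
#'   `eps_scaled` (kcal/mol).
#' @export
collapse_lj_categories <- function(structure, scale = 0.3) {
  cat_of <- element_category(structure$element, structure$serial)
  out <- purrr::map(CATEGORY_LABELS, function(lab) {
    sel <- cat_of == lab
    tibble(label = lab, n_atoms = sum(sel),
           rmin_mean = if (any(sel)) mean(2 * structure$lj_rmin_half[sel]) else 0,
           eps_scaled = if (any(sel)) mean(structure$lj_epsilon[sel]) * scale else 0)
  })
  out <- bind_rows(out)
  if (any(out$n_atoms == 0))
    warn(paste0("empty LJ categor", if (sum(out$n_atoms == 0) > 1) "ies: " else "y: ",
                paste(out$label[out$n_atoms == 0], collapse = ", "),
                " (maps for them will be skipped)"))
  out
}

#' Deposit a per-atom property onto a grid (cloud-in-cell)
#'
#' Trilinear (cloud-in-cell) deposition: each atom's weight is shared among
#' the eight surrounding nodes, so grid totals conserve the deposited sum
#' exactly.
#'
#' @param structure A [bd_structure()].
#' @param property `"charge"` or one of the category labels `"H"`, `"ON"`,
#'   `"CS"` (unit count per member atom).
#' @param frame Grid frame (list with `origin`, `spacing`, `dim`), e.g. from
#'   [grid_frame()].
#' @return A [grid_map()] of deposited weight per cell.
#' @export
deposit_density <- function(structure, property = "charge", frame) {
  if (identical(property, "charge")) {
    w <- structure$charge
    unit <- "e/cell"
    keep <- rep(TRUE, nrow(structure))
  } else if (property %in% CATEGORY_LABELS) {
    keep <- element_category(structure$element, structure$serial) == property
    w <- rep(1, sum(keep))
    unit <- "atoms/cell"
  } else {
    abort(paste0("unknown density property '", property, "'"))
  }
  pts <- coords_matrix(structure)[keep, , drop = FALSE]
  vals <- cpp_deposit_cic(pts, w, as.integer(frame$dim), frame$origin,
                          frame$spacing, as.integer(structure$serial[keep]))
  grid_map(array(vals, dim = frame$dim), origin = frame$origin,
           spacing = frame$spacing, unit = unit, out_of_bounds = "zero")
}

#' Debye-Hueckel (screened Coulomb) potential map
#'
#' Built-in uniform-dielectric fallback for an imported Poisson-Boltzmann
#' map: `V(r) = 332.0636 sum_i q_i exp(-|r - r_i| / lambda_D) /
#' (eps_s |r - r_i|)` within `cutoff`, with Debye length
#' `lambda_D = 3.04 / sqrt(I)` Angstrom for ionic strength `I` in molar
#' (`I = 0` disables screening). Nodes within 1 Angstrom of an atom centre
#' are clamped to `+/- cap`.
#'
#' @param structure A [bd_structure()] with charges.
#' @param frame Grid frame (see [grid_frame()]).
#' @param solvent_dielectric Relative solvent dielectric (default 78).
#' @param ionic_strength Molar ionic strength (default 0).
#' @param cutoff Pair cutoff in Angstrom (default 34).
#' @param cap Clamp magnitude, kcal/(mol e) (default 30).
#' @return A [grid_map()] in kcal/(mol e) with
#'   `attr(, "provenance") == "internal-screened-coulomb"`.
#' @export
screened_coulomb_map <- function(structure, frame, solvent_dielectric = 78,
                                 ionic_strength = 0, cutoff = 34, cap = 30) {
  if (ionic_strength < 0) abort("ionic strength must be >= 0")
  if (cutoff <= 0) abort("cutoff must be positive")
  lambda <- if (ionic_strength > 0) 3.04 / sqrt(ionic_strength) else -1
  vals <- cpp_coulomb_map(coords_matrix(structure), structure$charge,
                          as.integer(frame$dim), frame$origin, frame$spacing,
                          solvent_dielectric, lambda, cutoff, cap)
  out <- grid_map(array(vals, dim = frame$dim), origin = frame$origin,
                  spacing = frame$spacing, unit = "kcal/(mol e)",
                  out_of_bounds = "zero")
  attr(out, "provenance") <- "internal-screened-coulomb"
  out
}

#' Lennard-Jones potential map of a category probe
#'
#' Energy of a single spherical probe carrying a category's collapsed
#' parameters against every stationary atom within `cutoff`
#' (Lorentz-Berthelot combination, Rmin convention), clamped at `cap` so the
#' repulsive core stays finite everywhere.
#'
#' @param structure A [bd_structure()] with per-atom LJ parameters.
#' @param category One row of [collapse_lj_categories()] output.
#' @param frame Grid frame.
#' @param cutoff Pair cutoff in Angstrom (default 34).
#' @param cap Upper clamp in kcal/mol (default 30).
#' @return A [grid_map()] in kcal/mol.
#' @export
lj_potential_map <- function(structure, category, frame, cutoff = 34, cap = 30) {
  if (cap <= 0) abort("cap must be positive")
  vals <- cpp_lj_map(coords_matrix(structure), structure$lj_rmin_half,
                     structure$lj_epsilon, category$rmin_mean,
                     category$eps_scaled, as.integer(frame$dim), frame$origin,
                     frame$spacing, cutoff, cap)
  grid_map(array(vals, dim = frame$dim), origin = frame$origin,
           spacing = frame$spacing, unit = "kcal/mol", out_of_bounds = "zero")
}

#' Build the stationary body's full map set
#'
#' One electrostatic map (imported or screened-Coulomb) plus one LJ map per
#' non-empty collapsed category, all on a common frame.
#'
#' @param structure The stationary [bd_structure()].
#' @param frame Grid frame; defaults to [grid_frame()] with the cutoff as
#'   margin.
#' @param categories Output of [collapse_lj_categories()]; computed if
#'   missing.
#' @param elec_map Optional externally produced electrostatic [grid_map()]
#'   (e.g. via [read_dx()] from a Poisson-Boltzmann solver); when `NULL` the
#'   screened-Coulomb fallback is built.
#' @param cutoff,cap,solvent_dielectric,ionic_strength Passed to the map
#'   builders.
#' @param lj_scale Well-depth scale for [collapse_lj_categories()].
#' @return A `map_set`: list with `elec`, `lj` (named list of maps),
#'   `categories`, `provenance`, `frame`.
#' @export
build_map_set <- function(structure, frame = NULL, categories = NULL,
                          elec_map = NULL, cutoff = 34, cap = 30,
                          solvent_dielectric = 78, ionic_strength = 0,
                          lj_scale = 0.3) {
  if (is.null(frame)) frame <- grid_frame(structure, margin = cutoff)
  if (is.null(categories)) categories <- collapse_lj_categories(structure, scale = lj_scale)
  if (is.null(elec_map)) {
    elec <- screened_coulomb_map(structure, frame, solvent_dielectric,
                                 ionic_strength, cutoff, cap)
    provenance <- "internal-screened-coulomb"
  } else {
    elec <- elec_map
    provenance <- "imported-dx"
  }
  keep <- categories$n_atoms > 0
  lj <- lapply(which(keep), function(i)
    lj_potential_map(structure, categories[i, ], frame, cutoff, cap))
  names(lj) <- categories$label[keep]
  structure(list(elec = elec, lj = lj, categories = categories,
                 provenance = provenance, frame = frame),
            class = "map_set")
}

#' Build the mobile body's density set
#'
#' Charge and per-category particle-count grids deposited in the body frame,
#' plus the body's reference COM (rotations during BD are taken about it).
#'
#' @param structure The mobile [bd_structure()].
#' @param spacing Grid spacing in Angstrom (default 1).
#' @param margin Frame padding in Angstrom.
#' @return A `density_set`: list with `charge`, `lj` (named list of count
#'   grids), `com`, `frame`.
#' @export
build_density_set <- function(structure, spacing = 1, margin = 3) {
  frame <- grid_frame(structure, margin = margin, spacing = spacing)
  cats <- element_category(structure$element, structure$serial)
  lj <- lapply(CATEGORY_LABELS[CATEGORY_LABELS %in% cats], function(lab)
    deposit_density(structure, lab, frame))
  names(lj) <- CATEGORY_LABELS[CATEGORY_LABELS %in% cats]
  structure(list(charge = deposit_density(structure, "charge", frame),
                 lj = lj, com = structure_com(structure), frame = frame),
            class = "density_set")
}

# Pair a density set with a map set into the parallel (map, cells) lists the
# compiled propagator consumes. Cell positions are relative to the body COM.
pair_density_maps <- function(density, maps) {
  nonzero_cells <- function(g, com) {
    idx <- which(g$values != 0, arr.ind = TRUE)
    pos <- cbind(g$origin[1] + (idx[, 1] - 1) * g$spacing[1] - com[1],
                 g$origin[2] + (idx[, 2] - 1) * g$spacing[2] - com[2],
                 g$origin[3] + (idx[, 3] - 1) * g$spacing[3] - com[3])
    list(pos = pos, w = g$values[idx])
  }
  map_list <- list()
  cell_list <- list()
  add <- function(map, grid) {
    map_list[[length(map_list) + 1]] <<- c(grid_header(map), list(values = as.numeric(map$values)))
    cell_list[[length(cell_list) + 1]] <<- nonzero_cells(grid, density$com)
  }
  add(maps$elec, density$charge)
  for (lab in names(density$lj)) {
    if (!lab %in% names(maps$lj))
      abort(paste0("density category '", lab, "' has no matching LJ map"))
    add(maps$lj[[lab]], density$lj[[lab]])
  }
  list(maps = map_list, cells = cell_list)
}
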