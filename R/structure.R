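# Atomic structures as tibbles. A bd_structure is a tibble with one row per
# atom carrying position, partial charge, LJ parameters and vdW radius -- the
# per-atom quantities every downstream stage (maps, densities, energies,
# pore profiles) consumes.

#' Build an atomic structure tibble
#'
#' A `bd_structure` is a tibble subclass with columns `serial`, `name`,
#' `element`, `resname`, `resid`, `chain`, `x`, `y`, `z` (Angstrom), `charge`
#' (e), `lj_rmin_half` (Rmin/2, Angstrom), `lj_epsilon` (well depth magnitude,
#' kcal/mol) and `vdw_radius` (Angstrom).
#'
#' @param atoms A data frame with the columns above (missing `element` is
#'   inferred from the first letter of `name`; missing LJ columns default 0;
#'   missing `chain` defaults `"A"`).
#' @param title Optional title string.
#' @return A `bd_structure` tibble.
#' @export
bd_structure <- function(atoms, title = "") {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) abort("a structure must contain at least one atom")
  if (!"element" %in% names(atoms)) {
    atoms$element <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                         sub("^[0-9]+", "", atoms$name)), 1, 1))
  }
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"lj_rmin_half" %in% names(atoms)) atoms$lj_rmin_half <- 0
  if (!"lj_epsilon" %in% names(atoms)) atoms$lj_epsilon <- 0
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "x", "y", "z", "charge", "lj_rmin_half", "lj_epsilon", "vdw_radius")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0)
    abort(paste0("structure is missing columns: ", paste(missing_cols, collapse = ", ")))
  atoms <- atoms[need]
  if (anyDuplicated(atoms$serial))
    abort("duplicate atom serials in structure")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort("non-finite atom positions")
  if (any(atoms$vdw_radius <= 0))
    abort("vdw_radius must be positive for every atom")
  if (any(atoms$lj_rmin_half < 0) || any(atoms$lj_epsilon < 0))
    abort("LJ parameters must be non-negative (epsilon stored as magnitude)")
  structure(atoms, class = c("bd_structure", class(tibble())), title = title)
}

#' @export
print.bd_structure <- function(x, ...) {
  cat("# A bd_structure: ", nrow(x), " atoms",
      if (nzchar(attr(x, "title"))) paste0(" (", attr(x, "title"), ")"), "\n",
      sep = "")
  NextMethod()
}

#' Total charge of a structure
#' @param structure A [bd_structure()].
#' @return Total charge in e.
#' @export
total_charge <- function(structure) sum(structure$charge)

#' Geometric centre of mass (unweighted mean position)
#' @param structure A [bd_structure()] or data frame with `x`, `y`, `z`.
#' @return Numeric length-3 vector.
#' @export
structure_com <- function(structure) {
  c(mean(structure$x), mean(structure$y), mean(structure$z))
}

coords_matrix <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}

#' Read a PQR structure
#'
#' Whitespace-separated ATOM records; the last two numeric columns are the
#' partial charge (e) and radius (Angstrom). Records may or may not carry a
#' chain identifier. LJ parameters default to zero unless a sidecar parameter
#' table is supplied (see [read_param_table()] and [apply_parameters()]).
#'
#' @param path Path to a PQR file.
#' @param params Optional parameter table from [read_param_table()].
#' @return A [bd_structure()].
#' @export
read_pqr <- function(path, params = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- grepl("^(ATOM|HETATM)", lines)
  if (!any(keep)) abort(paste0("no ATOM records in ", path))
  idx <- which(keep)
  rows <- lapply(seq_along(idx), function(i) {
    ln <- idx[i]
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    # ATOM serial name resname [chain] resid x y z charge radius
    if (!(length(tok) %in% c(10L, 11L)))
      abort(paste0("malformed ATOM record at line ", ln, ": expected 10 or 11 fields, found ", length(tok)))
    nt <- length(tok)
    num <- suppressWarnings(as.numeric(tok[(nt - 5):nt]))
    if (anyNA(num) || is.na(suppressWarnings(as.integer(tok[2]))))
      abort(paste0("malformed numeric field at line ", ln))
    tibble(
      serial = as.integer(tok[2]), name = tok[3], resname = tok[4],
      chain = if (nt == 11L) tok[5] else "A",
      resid = as.integer(num[1]),
      x = num[2], y = num[3], z = num[4],
      charge = num[5], vdw_radius = num[6]
    )
  })
  atoms <- bind_rows(rows)
  out <- bd_structure(atoms, title = basename(path))
  if (!is.null(params)) out <- apply_parameters(out, params)
  out
}

#' Write a PQR structure
#'
#' @param structure A [bd_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(structure, path) {
  lines <- sprintf("ATOM  %6d %-4s %-4s %s %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
                   structure$serial, structure$name, structure$resname,
                   structure$chain, structure$resid,
                   structure$x, structure$y, structure$z,
                   structure$charge, structure$vdw_radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a sidecar LJ/charge parameter table
#'
#' A delimited text table with header columns `resname`, `name`, `charge`,
#' `lj_rmin_half`, `lj_epsilon`, `vdw_radius` mapping (residue name, atom
#' name) to per-atom parameters, as assigned by a force field the package
#' does not bundle.
#'
#' @param path Path to the table (whitespace- or comma-delimited).
#' @return A tibble of parameters.
#' @export
read_param_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1)
  df <- if (grepl(",", first)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  need <- c("resname", "name", "charge", "lj_rmin_half", "lj_epsilon", "vdw_radius")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    abort(paste0("parameter table missing columns: ", paste(missing_cols, collapse = ", ")))
  as_tibble(df[need])
}

#' Attach sidecar parameters to a structure
#'
#' Joins by (resname, name) and overwrites `charge`, `lj_rmin_half`,
#' `lj_epsilon` and `vdw_radius`.
#'
#' @param structure A [bd_structure()].
#' @param params Tibble from [read_param_table()].
#' @return The updated [bd_structure()].
#' @export
apply_parameters <- function(structure, params) {
  key <- paste(structure$resname, structure$name)
  pkey <- paste(params$resname, params$name)
  hit <- match(key, pkey)
  if (anyNA(hit)) {
    bad <- structure$serial[which(is.na(hit))[1]]
    abort(paste0("no parameters for atom serial ", bad, " (",
                 key[which(is.na(hit))[1]], ")"))
  }
  structure$charge <- params$charge[hit]
  structure$lj_rmin_half <- params$lj_rmin_half[hit]
  structure$lj_epsilon <- params$lj_epsilon[hit]
  structure$vdw_radius <- params$vdw_radius[hit]
  structure
}

#' Read a plain PDB with a sidecar parameter table
#'
#' Plain PDB files carry no charges or radii, so a parameter table is
#' mandatory. Parsing is delegated to \pkg{bio3d}.
#'
#' @param path Path to a PDB file.
#' @param params Tibble from [read_param_table()].
#' @return A [bd_structure()].
#' @export
read_pdb_structure <- function(path, params) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    abort("reading PDB requires the bio3d package")
  if (missing(params) || is.null(params))
    abort("plain PDB input requires a sidecar parameter table (charges and radii)")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  atoms <- tibble(
    serial = as.integer(a$eleno), name = a$elety, resname = a$resid,
    resid = as.integer(a$resno),
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    charge = 0, vdw_radius = 1.5
  )
  apply_parameters(bd_structure(atoms, title = basename(path)), params)
}
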