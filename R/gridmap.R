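# Regular 3-D scalar grids: the container for electrostatic/LJ potential maps
# and charge/particle density grids. In memory, values are an R array indexed
# [i, j, k] along (x, y, z); on disk (OpenDX) the z index varies fastest.

#' Construct a regular 3-D scalar grid
#'
#' @param values A 3-D numeric array, indexed `[i, j, k]` along (x, y, z).
#' @param origin Numeric length-3: coordinates of node `[1, 1, 1]` (Angstrom).
#' @param spacing Numeric length-3 (or scalar) grid spacing (Angstrom),
#'   default 1 along each axis.
#' @param unit Unit string for the stored values (e.g. `"kcal/mol"`,
#'   `"e/cell"`).
#' @param out_of_bounds Policy for evaluation outside the grid: `"zero"`,
#'   `"clamp"` (clamp to edge) or `"error"`.
#' @return A `grid_map` object.
#' @export
grid_map <- function(values, origin, spacing = 1,
                     unit = "", out_of_bounds = c("zero", "clamp", "error")) {
  out_of_bounds <- match.arg(out_of_bounds)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) abort("grid spacing must be positive")
  if (length(dim(values)) != 3) abort("values must be a 3-D array")
  if (any(dim(values) < 2)) abort("each grid dimension needs at least 2 nodes")
  if (!all(is.finite(values))) abort("grid values must be finite")
  structure(
    list(values = values, origin = as.numeric(origin),
         spacing = as.numeric(spacing), dim = dim(values),
         unit = unit, out_of_bounds = out_of_bounds),
    class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat("# grid_map ", paste(x$dim, collapse = " x "),
      " nodes, spacing (", paste(signif(x$spacing, 4), collapse = ", "),
      ") A, origin (", paste(signif(x$origin, 4), collapse = ", "), ")",
      if (nzchar(x$unit)) paste0(" [", x$unit, "]"), "\n", sep = "")
  cat("  values in [", signif(min(x$values), 5), ", ",
      signif(max(x$values), 5), "], out-of-bounds: ", x$out_of_bounds,
      "\n", sep = "")
  invisible(x)
}

oob_policy_code <- function(map) {
  match(map$out_of_bounds, c("zero", "clamp", "error")) - 1L
}

grid_header <- function(map) {
  list(dim = as.integer(map$dim), origin = map$origin, spacing = map$spacing)
}

#' Node coordinates along each axis of a grid
#' @param map A [grid_map()].
#' @return List of numeric vectors `x`, `y`, `z`.
#' @export
grid_axes <- function(map) {
  list(x = map$origin[1] + (seq_len(map$dim[1]) - 1) * map$spacing[1],
       y = map$origin[2] + (seq_len(map$dim[2]) - 1) * map$spacing[2],
       z = map$origin[3] + (seq_len(map$dim[3]) - 1) * map$spacing[3])
}

#' Trilinear interpolation of a grid at arbitrary points
#'
#' @param map A [grid_map()].
#' @param points Numeric length-3 vector or n x 3 matrix of coordinates.
#' @return Numeric vector of interpolated values.
#' @export
interpolate <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  cpp_grid_interp(grid_header(map), as.numeric(map$values),
                  points, oob_policy_code(map))
}

#' Analytic gradient of the trilinear interpolant
#'
#' The returned gradient is the exact derivative of the piecewise-trilinear
#' field [interpolate()] evaluates, so forces computed from it are the exact
#' negative gradient of the interpolated energy.
#'
#' @inheritParams interpolate
#' @return n x 3 matrix of gradient vectors (value units per Angstrom).
#' @export
gradient <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  cpp_grid_gradient(grid_header(map), as.numeric(map$values),
                    points, oob_policy_code(map))
}

#' Default grid frame enclosing a structure
#'
#' @param structure A [bd_structure()] (or anything with `x`, `y`, `z`).
#' @param margin Padding beyond the atomic extent (Angstrom).
#' @param spacing Grid spacing (Angstrom), default 1.
#' @return A list with `origin`, `spacing` and `dim`, usable as a grid frame.
#' @export
grid_frame <- function(structure, margin = 5, spacing = 1) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  lo <- c(min(structure$x), min(structure$y), min(structure$z)) - margin
  hi <- c(max(structure$x), max(structure$y), max(structure$z)) + margin
  dim <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(origin = lo, spacing = spacing, dim = dim)
}
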