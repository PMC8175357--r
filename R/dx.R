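# OpenDX scalar-grid I/O ("regular positions, regular connections"), the
# interchange format of Poisson-Boltzmann solvers. DX stores values with the
# z index varying fastest; in-memory grid_map arrays have x fastest, so both
# directions permute explicitly.

#' Read an OpenDX scalar grid
#'
#' Supports the regular-positions / regular-connections dialect written by
#' Poisson-Boltzmann solvers (diagonal `delta` rows only).
#'
#' @param path Path to a `.dx` file.
#' @param unit Unit string to attach to the values.
#' @param out_of_bounds Out-of-bounds policy for the resulting map.
#' @return A [grid_map()].
#' @export
read_dx <- function(path, unit = "", out_of_bounds = "zero") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  counts_line <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(counts_line) == 0)
    abort("unsupported DX format: no regular gridpositions object")
  nums <- function(s) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]]))
    v[!is.na(v)]
  }
  cnt <- utils::tail(nums(gsub(".*counts", "", counts_line[1])), 3)
  dim <- as.integer(cnt)
  origin <- utils::tail(nums(grep("^origin", lines, value = TRUE)[1]), 3)
  deltas <- grep("^delta", lines, value = TRUE)
  if (length(deltas) != 3) abort("unsupported DX format: expected 3 delta rows")
  dmat <- t(vapply(deltas, function(s) utils::tail(nums(s), 3), numeric(3)))
  if (any(abs(dmat[upper.tri(dmat) | lower.tri(dmat)]) > 1e-12))
    abort("unsupported DX format: non-axis-aligned (non-diagonal) deltas")
  spacing <- diag(dmat)
  data_at <- grep("data follows", lines)
  if (length(data_at) == 0) abort("unsupported DX format: no 'data follows' array")
  n_expect <- prod(dim)
  body <- lines[(data_at[1] + 1):length(lines)]
  body <- body[!grepl("^(object|attribute|component|end)", body)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "[[:space:]]+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) < n_expect)
    abort(paste0("truncated DX array: expected ", n_expect, " values, found ",
                 length(vals)))
  vals <- vals[seq_len(n_expect)]
  # DX order: z fastest -> fill (z, y, x) then permute to (x, y, z)
  arr <- aperm(array(vals, dim = rev(dim)), c(3, 2, 1))
  grid_map(arr, origin = origin, spacing = spacing, unit = unit,
           out_of_bounds = out_of_bounds)
}

#' Write an OpenDX scalar grid
#'
#' @param map A [grid_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(map, path) {
  dim <- map$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by rigidbd",
    if (nzchar(map$unit)) paste0("# unit: ", map$unit),
    sprintf("object 1 class gridpositions counts %d %d %d", dim[1], dim[2], dim[3]),
    sprintf("origin %.10g %.10g %.10g", map$origin[1], map$origin[2], map$origin[3]),
    sprintf("delta %.10g 0 0", map$spacing[1]),
    sprintf("delta 0 %.10g 0", map$spacing[2]),
    sprintf("delta 0 0 %.10g", map$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", dim[1], dim[2], dim[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(dim))
  ), con)
  vals <- as.numeric(aperm(map$values, c(3, 2, 1))) # z fastest on disk
  n <- length(vals)
  rows <- split(vals, ceiling(seq_len(n) / 3))
  writeLines(vapply(rows, function(v) paste(sprintf("%.10e", v), collapse = " "),
                    character(1)), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
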