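# Rigid-body trajectories: tidy tables of time-stamped poses. BD states are
# a COM translation plus an orientation quaternion, so a columnar text format
# (not a per-atom binary MD format) is the natural container.

#' Build a rigid-body trajectory tibble
#'
#' @param frames A data frame with columns `time_ns`, `x`, `y`, `z` (COM,
#'   Angstrom) and `qw`, `qx`, `qy`, `qz` (unit quaternion, body-to-lab).
#'   An optional `replica` column groups independent runs.
#' @param mobile_label,stationary_label Labels of the two bodies.
#' @param quat_tol Tolerance on `|q| - 1` before an error is raised.
#' @return A `bd_trajectory` tibble.
#' @export
bd_trajectory <- function(frames, mobile_label = "mobile",
                          stationary_label = "stationary", quat_tol = 1e-6) {
  frames <- as_tibble(frames)
  need <- c("time_ns", "x", "y", "z", "qw", "qx", "qy", "qz")
  missing_cols <- setdiff(need, names(frames))
  if (length(missing_cols) > 0)
    abort(paste0("trajectory is missing columns: ", paste(missing_cols, collapse = ", ")))
  qn <- sqrt(frames$qw^2 + frames$qx^2 + frames$qy^2 + frames$qz^2)
  if (any(abs(qn - 1) > quat_tol))
    abort(paste0("non-unit quaternion at frame ",
                 which(abs(qn - 1) > quat_tol)[1],
                 " (|q| = ", signif(qn[which(abs(qn - 1) > quat_tol)[1]], 6), ")"))
  check_one <- function(t) {
    if (length(t) > 1 && any(diff(t) <= 0))
      abort("trajectory times must be strictly increasing")
  }
  if ("replica" %in% names(frames)) {
    tapply(frames$time_ns, frames$replica, check_one)
  } else {
    check_one(frames$time_ns)
  }
  structure(frames, class = c("bd_trajectory", class(tibble())),
            mobile_label = mobile_label, stationary_label = stationary_label)
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat("# A bd_trajectory: ", nrow(x), " frames (",
      attr(x, "mobile_label"), " vs ", attr(x, "stationary_label"), ")\n",
      sep = "")
  NextMethod()
}

#' Read a columnar rigid-body trajectory
#'
#' Plain text with a header row `time_ns x y z qw qx qy qz` (optionally a
#' leading `replica` column); `#` comment lines may carry labels as
#' `# mobile: <label>` / `# stationary: <label>`.
#'
#' @param path Path to the trajectory file.
#' @return A [bd_trajectory()].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  comments <- lines[grepl("^#", lines)]
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), comments, value = TRUE)
    if (length(hit) > 0) trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1])) else key
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  bd_trajectory(df, mobile_label = grab("mobile"),
                stationary_label = grab("stationary"))
}

#' Write a columnar rigid-body trajectory
#'
#' Numeric fields are written with 12 significant digits so that
#' read-back reproduces poses to well below the quaternion tolerance.
#'
#' @param traj A [bd_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# mobile: ", attr(traj, "mobile_label")),
               paste0("# stationary: ", attr(traj, "stationary_label"))), con)
  cols <- intersect(c("replica", "time_ns", "x", "y", "z", "qw", "qx", "qy", "qz"),
                    names(traj))
  writeLines(paste(cols, collapse = " "), con)
  body <- do.call(paste, c(lapply(cols, function(cn) {
    v <- traj[[cn]]
    if (cn == "replica") format(v) else sprintf("%.12g", v)
  }), sep = " "))
  writeLines(body, con)
  invisible(path)
}

# frames of one trajectory as a poses matrix (x, y, z, qw, qx, qy, qz)
poses_matrix <- function(traj) {
  as.matrix(traj[, c("x", "y", "z", "qw", "qx", "qy", "qz")])
}
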