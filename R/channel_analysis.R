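# Permeation and geometry analyses: complete-crossing counting by a
# three-state (below / inside / above) machine, ionic current I = N q / tau,
# HOLE-style largest-free-sphere pore radius profiles, and geometric
# hydrogen-bond detection.

#' Build an ion-track table
#'
#' @param tracks Data frame with columns `ion_id`, `species` (`"Na+"` or
#'   `"Cl-"`), `time_ns`, `z` (optionally `x`, `y`).
#' @param slab Length-2 membrane bounds `(lower, upper)` in Angstrom.
#' @return An `ion_tracks` tibble with the slab stored as an attribute.
#' @export
ion_tracks <- function(tracks, slab) {
  tracks <- as_tibble(tracks)
  need <- c("ion_id", "species", "time_ns", "z")
  missing_cols <- setdiff(need, names(tracks))
  if (length(missing_cols) > 0)
    abort(paste0("ion tracks missing columns: ", paste(missing_cols, collapse = ", ")))
  if (!all(is.finite(tracks$z))) abort("non-finite z in ion tracks")
  if (slab[1] >= slab[2]) abort("slab lower bound must be below upper bound")
  structure(tracks, class = c("ion_tracks", class(tibble())), slab = slab)
}

ion_charge <- function(species) {
  out <- dplyr::case_when(species == "Na+" ~ Q_ELEMENTARY,
                          species == "Cl-" ~ -Q_ELEMENTARY,
                          TRUE ~ NA_real_)
  if (anyNA(out)) abort(paste0("unknown ion species: ",
                               paste(unique(species[is.na(out)]), collapse = ", ")))
  out
}

# compressed side sequence of one z track with the first sample index at
# which each side was reached
side_sequence <- function(z, slab) {
  r <- ifelse(z < slab[1], -1L, ifelse(z > slab[2], 1L, 0L))
  nz <- which(r != 0L)
  if (length(nz) == 0) return(list(s = integer(), idx = integer()))
  s <- r[nz]
  keep <- c(TRUE, diff(s) != 0L)
  list(s = s[keep], idx = nz[keep])
}

#' Count complete channel crossings per ion
#'
#' A crossing is counted only when an ion moves all the way from one side of
#' the membrane slab to the other (below -> inside -> above counts up;
#' above -> inside -> below counts down); excursions into the slab that
#' return to the same side count zero.
#'
#' @param tracks An [ion_tracks()] table (or a bare numeric z vector).
#' @param slab Membrane bounds; defaults to the attribute on `tracks`.
#' @return Tibble with `ion_id`, `species`, `n_up`, `n_down`.
#' @export
count_crossings <- function(tracks, slab = NULL) {
  if (is.numeric(tracks) && is.null(dim(tracks))) {
    if (is.null(slab)) abort("slab bounds are required for a bare z vector")
    tracks <- ion_tracks(tibble(ion_id = 1L, species = "Na+",
                                time_ns = seq_along(tracks), z = tracks), slab)
  }
  slab <- slab %||% attr(tracks, "slab")
  if (is.null(slab)) abort("slab bounds are required")
  if (!all(is.finite(tracks$z))) abort("non-finite z in ion tracks")
  tracks |>
    group_by(.data$ion_id, .data$species) |>
    summarise(
      n_up = {
        s <- side_sequence(.data$z[order(.data$time_ns)], slab)$s
        if (length(s) < 2) 0L else sum(s[-1] == 1L & s[-length(s)] == -1L)
      },
      n_down = {
        s <- side_sequence(.data$z[order(.data$time_ns)], slab)$s
        if (length(s) < 2) 0L else sum(s[-1] == -1L & s[-length(s)] == 1L)
      },
      .groups = "drop")
}

#' Individual crossing events with times
#'
#' @inheritParams count_crossings
#' @return Tibble with `ion_id`, `species`, `time_ns` (arrival on the far
#'   side) and `direction` (+1 up, -1 down).
#' @export
crossing_events <- function(tracks, slab = NULL) {
  slab <- slab %||% attr(tracks, "slab")
  rows <- tracks |>
    group_by(.data$ion_id, .data$species) |>
    dplyr::group_map(function(df, key) {
      df <- df[order(df$time_ns), ]
      sq <- side_sequence(df$z, slab)
      if (length(sq$s) < 2) return(NULL)
      flips <- which(sq$s[-1] != sq$s[-length(sq$s)]) + 1
      tibble(ion_id = key$ion_id, species = key$species,
             time_ns = df$time_ns[sq$idx[flips]],
             direction = sq$s[flips])
    })
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble(ion_id = integer(), species = character(),
                  time_ns = numeric(), direction = integer())
  arrange(out, .data$time_ns)
}

#' Ionic current from crossing counts
#'
#' `I = N q / tau` per species with signed elementary charges
#' (+1.60217662e-19 C for Na+, the negative for Cl-) and net counts signed
#' by direction (up = +); the total is the sum over species. A net anion
#' crossing down therefore contributes the same current as a net cation
#' crossing up.
#'
#' @param counts Tibble with `species`, `n_up`, `n_down` (e.g. from
#'   [count_crossings()]; multiple ions per species are summed).
#' @param tau_s Observation interval in seconds.
#' @param events Optional [crossing_events()] table stored for cumulative
#'   plots.
#' @return A `current_result` object.
#' @export
compute_current <- function(counts, tau_s, events = NULL) {
  if (tau_s <= 0) abort("tau must be positive")
  per <- counts |>
    group_by(.data$species) |>
    summarise(n_up = sum(.data$n_up), n_down = sum(.data$n_down),
              .groups = "drop") |>
    mutate(net = .data$n_up - .data$n_down,
           charge_C = ion_charge(.data$species),
           current_A = .data$net * .data$charge_C / tau_s)
  structure(list(per_species = per, total_A = sum(per$current_A),
                 tau_s = tau_s, events = events),
            class = "current_result")
}

#' @export
print.current_result <- function(x, ...) {
  cat("# current_result: I =", signif(x$total_A, 6), "A (",
      signif(x$total_A * 1e12, 6), "pA ) over tau =", x$tau_s, "s\n")
  print(x$per_species)
  invisible(x)
}

#' Crossing counts + current in one call
#'
#' @inheritParams count_crossings
#' @param tau_s Observation interval in seconds; defaults to the track span.
#' @return A `current_result`.
#' @export
ionic_current <- function(tracks, slab = NULL, tau_s = NULL) {
  slab <- slab %||% attr(tracks, "slab")
  tau_s <- tau_s %||% (diff(range(tracks$time_ns)) * 1e-9)
  compute_current(count_crossings(tracks, slab), tau_s,
                  events = crossing_events(tracks, slab))
}

#' HOLE-style pore radius profile
#'
#' At each z along the channel axis the profile reports the radius of the
#' largest probe sphere, centred in that plane, that touches no atom's vdW
#' surface: `r(c) = min_i (|c - x_i| - vdw_i)`, maximised over the lateral
#' centre c by a coarse grid search (0.5 Angstrom) followed by Nelder-Mead
#' refinement, with the centre seeded from the previous slice. The radius is
#' clamped at `clamp` where the pore opens to bulk.
#'
#' @param structure A [bd_structure()] with vdW radii.
#' @param z_range Length-2 z limits; defaults to the atomic extent.
#' @param z_step Slice spacing (default 1 Angstrom).
#' @param axis Optional function `z -> c(x, y)` giving the axis; the default
#'   fits a least-squares line through per-slice atom centroids.
#' @param lateral_search Half-width of the lateral grid search (Angstrom).
#' @param clamp Bulk clamp radius (default 15 Angstrom).
#' @return A `pore_profile` tibble with `z`, `radius`, `cx`, `cy`, `bulk`
#'   (flag set where no atoms constrain the slice).
#' @export
pore_profile <- function(structure, z_range = NULL, z_step = 1, axis = NULL,
                         lateral_search = 3, clamp = 15) {
  X <- coords_matrix(structure)
  vdw <- structure$vdw_radius
  if (is.null(z_range)) z_range <- range(X[, 3])
  zs <- seq(z_range[1], z_range[2], by = z_step)
  if (is.null(axis)) {
    sl <- cut(X[, 3], breaks = pmax(3, min(12, floor(diff(range(X[, 3]))))))
    cen <- stats::aggregate(X[, 1:2], by = list(sl), FUN = mean)
    zc <- stats::aggregate(X[, 3], by = list(sl), FUN = mean)$x
    fx <- lm(cen[, 2] ~ zc); fy <- lm(cen[, 3] ~ zc)
    axis <- function(z) c(coef(fx)[1] + coef(fx)[2] * z,
                          coef(fy)[1] + coef(fy)[2] * z)
  }
  free_r <- function(cx, cy, z, sel) {
    d <- sqrt((X[sel, 1] - cx)^2 + (X[sel, 2] - cy)^2 + (X[sel, 3] - z)^2) - vdw[sel]
    min(d)
  }
  prev <- NULL
  rows <- lapply(zs, function(z) {
    sel <- which(abs(X[, 3] - z) <= clamp + max(vdw))
    if (length(sel) == 0)
      return(tibble(z = z, radius = clamp, cx = NA_real_, cy = NA_real_,
                    bulk = TRUE))
    seed <- prev %||% axis(z)
    off <- seq(-lateral_search, lateral_search, by = 0.5)
    g <- expand.grid(cx = seed[1] + off, cy = seed[2] + off)
    rg <- vapply(seq_len(nrow(g)), function(i) free_r(g$cx[i], g$cy[i], z, sel),
                 numeric(1))
    best <- g[which.max(rg), ]
    opt <- optim(c(best$cx, best$cy),
                 function(c2) -free_r(c2[1], c2[2], z, sel),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 500))
    r <- max(0, -opt$value)
    prev <<- opt$par
    tibble(z = z, radius = min(r, clamp), cx = opt$par[1], cy = opt$par[2],
           bulk = r >= clamp)
  })
  structure(bind_rows(rows), class = c("pore_profile", class(tibble())))
}

#' Geometric hydrogen-bond detection
#'
#' A bond is reported when the donor-acceptor distance is below
#' `dist_cutoff` (default 3 Angstrom) and the D-H-A angle, measured at the
#' hydrogen, exceeds `angle_cutoff` (default 120 degrees).
#'
#' @param structure A [bd_structure()] (any table with `x`, `y`, `z` works).
#' @param donors Integer row indices of donor heavy atoms.
#' @param hydrogens Integer row indices of the hydrogen bound to each donor
#'   (`NA` skips that donor with a warning).
#' @param acceptors Integer row indices of acceptor atoms.
#' @param dist_cutoff,angle_cutoff Geometric criteria.
#' @return Tibble with `donor`, `hydrogen`, `acceptor`, `distance_DA`,
#'   `angle_DHA`.
#' @export
hydrogen_bonds <- function(structure, donors, hydrogens, acceptors,
                           dist_cutoff = 3.0, angle_cutoff = 120) {
  X <- coords_matrix(structure)
  if (any(is.na(hydrogens))) {
    warn(paste0("skipping ", sum(is.na(hydrogens)),
                " donor(s) without a bound hydrogen"))
    donors <- donors[!is.na(hydrogens)]
    hydrogens <- hydrogens[!is.na(hydrogens)]
  }
  rows <- lapply(seq_along(donors), function(i) {
    D <- X[donors[i], ]; H <- X[hydrogens[i], ]
    A <- X[acceptors, , drop = FALSE]
    dDA <- sqrt(colSums((t(A) - D)^2))
    hd <- D - H
    ha <- sweep(A, 2, H)
    cosang <- (ha %*% hd) /
      (sqrt(sum(hd^2)) * sqrt(rowSums(ha^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hit <- which(dDA < dist_cutoff & ang > angle_cutoff &
                   acceptors != donors[i] & acceptors != hydrogens[i])
    if (length(hit) == 0) return(NULL)
    tibble(donor = donors[i], hydrogen = hydrogens[i],
           acceptor = acceptors[hit], distance_DA = dDA[hit],
           angle_DHA = ang[hit])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble(donor = integer(), hydrogen = integer(),
                  acceptor = integer(), distance_DA = numeric(),
                  angle_DHA = numeric())
  out
}
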