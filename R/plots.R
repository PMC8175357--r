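# ggplot2 front-ends for the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_path
#'   geom_step geom_point labs scale_fill_viridis_c coord_equal theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a hot-spot density map
#'
#' @param object A [hotspot_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hotspot_density
#' @export
autoplot.hotspot_density <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$x, y = .data$y, fill = .data$density)) +
    geom_raster() +
    scale_fill_viridis_c(name = expression(rho(x, y))) +
    coord_equal() +
    labs(x = "x (Å)", y = "y (Å)",
         title = "Anchor COM occupancy density") +
    theme_minimal()
}

#' Plot a pore radius profile
#'
#' @param object A [pore_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pore_profile
#' @export
autoplot.pore_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$z, y = .data$radius)) +
    geom_line() +
    geom_point(aes(shape = .data$bulk), show.legend = FALSE) +
    labs(x = "z (Å)", y = "pore radius (Å)",
         title = "Pore radius profile") +
    theme_minimal()
}

#' Plot an anchoring potential
#'
#' @param object A `z_potential` from [boltzmann_invert()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot z_potential
#' @export
autoplot.z_potential <- function(object, ...) {
  lab <- attr(object, "label")
  ggplot(object, aes(x = .data$z, y = .data$U)) +
    geom_line() +
    labs(x = "z (Å)", y = "U (kcal/mol)",
         title = paste0("Boltzmann-inverted anchoring potential",
                        if (nzchar(lab)) paste0(" (", lab, ")"))) +
    theme_minimal()
}

#' Plot cumulative crossing events
#'
#' @param object A `current_result` built with events (see
#'   [ionic_current()]).
#' @param ... Unused.
#' @return A ggplot of the cumulative net crossings per species.
#' @method autoplot current_result
#' @export
autoplot.current_result <- function(object, ...) {
  ev <- object$events
  if (is.null(ev) || nrow(ev) == 0)
    abort("no crossing events stored; build the result with ionic_current()")
  cum <- ev |>
    group_by(.data$species) |>
    arrange(.data$time_ns, .by_group = TRUE) |>
    mutate(net = cumsum(.data$direction)) |>
    ungroup()
  ggplot(cum, aes(x = .data$time_ns, y = .data$net, colour = .data$species)) +
    geom_step() +
    labs(x = "time (ns)", y = "cumulative net crossings") +
    theme_minimal()
}

#' Plot the lateral path of a BD trajectory
#'
#' @param object A [bd_trajectory()].
#' @param ... Unused.
#' @return A ggplot of the COM (x, y) path per replica.
#' @method autoplot bd_trajectory
#' @export
autoplot.bd_trajectory <- function(object, ...) {
  df <- as_tibble(object)
  if (!"replica" %in% names(df)) df$replica <- 1L
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$time_ns,
                 group = .data$replica)) +
    geom_path() +
    coord_equal() +
    scale_fill_viridis_c() +
    labs(x = "x (Å)", y = "y (Å)", colour = "t (ns)") +
    theme_minimal()
}
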