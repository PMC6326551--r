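#' Plot a radial distribution function
#'
#' @param object An `rdf_profile` from [rdf()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rdf_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "r (nm)", y = "g(r)") +
    ggplot2::theme_minimal()
}

#' Plot a cylindrical number-density map
#'
#' @param object A `radial_density_map` from [density_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radial_density_map <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$z,
                               fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "distance from NP axis (nm)",
                  y = "z - midplane (nm)",
                  fill = expression(rho ~ (nm^-3))) +
    ggplot2::theme_minimal()
}

#' Plot the insertion free-energy landscape
#'
#' States are drawn in pathway order at their cumulative free energy;
#' barrier peaks are marked distinctly from minima.  The rendering is
#' schematic (state index, not a reaction coordinate).
#'
#' @param object An `np_landscape` from [assemble_landscape()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.np_landscape <- function(object, ...) {
  st <- object$states
  ggplot2::ggplot(st, ggplot2::aes(x = .data$index,
                                   y = .data$cumulative_dg)) +
    ggplot2::geom_step(direction = "mid", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$kind), size = 3) +
    ggplot2::scale_shape_manual(values = c(minimum = 16, barrier = 4)) +
    ggplot2::scale_x_continuous(breaks = st$index) +
    ggplot2::labs(x = "state", y = expression(Delta * G ~ "(kcal/mol)")) +
    ggplot2::theme_minimal()
}

#' Plot the core-depth trend
#'
#' @param object A `depth_trend` from [core_depth_trend()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_trend <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n_flipped,
                                            y = .data$z)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "flipped ligands", y = "core - midplane distance (nm)") +
    ggplot2::theme_minimal()
}

#' Plot coordination number against end-group height
#'
#' @param records Tibble of [coordination()] rows (one per ligand).
#' @return A ggplot of coordination number vs `d_z` with error bars.
#' @export
plot_coordination <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$dz_mean,
                                        y = .data$coordination_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$coordination_mean - .data$coordination_error,
      ymax = .data$coordination_mean + .data$coordination_error),
      width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$dz_mean - .data$dz_error,
      xmax = .data$dz_mean + .data$dz_error),
      height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(d[z] ~ "(nm)"),
                  y = "coordination number") +
    ggplot2::theme_minimal()
}
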