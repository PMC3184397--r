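#' Plot a perturbation trajectory
#'
#' Time course of the GSH/GSSG ratio (relative to its pre-perturbation value)
#' after the oxidative dose, with the recovery threshold drawn as a dashed
#' line.
#'
#' @param object A `redox_trajectory`.
#' @param relative Plot the ratio relative to its initial value (default
#'   TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot redox_trajectory
#' @export
autoplot.redox_trajectory <- function(object, relative = TRUE, ...) {
  r0 <- attr(object, "initial_ratio")
  theta <- attr(object, "theta") %||% 0.99
  df <- tibble::tibble(time = object$time / 60,
                       ratio = object$ratio_gsh_gssg / if (relative) r0 else 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$ratio)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = theta * if (relative) 1 else r0,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time after perturbation (min)",
                  y = if (relative) "GSH/GSSG (relative to initial)"
                      else "GSH/GSSG") +
    ggplot2::theme_minimal()
}

#' Plot enzyme activity time courses
#'
#' @param traj A `redox_trajectory`.
#' @param enzymes Reactions to show, see [enzyme_activity_series()].
#' @param relative Normalise each flux to its pre-perturbation value.
#' @return A ggplot object.
#' @export
plot_enzyme_activity <- function(traj, enzymes = c("G6PD", "CAT", "GSHpx"),
                                 relative = TRUE) {
  long <- enzyme_activity_series(traj, enzymes)
  if (relative) {
    base <- attr(traj, "steady_fluxes")
    long$flux <- long$flux / base[as.character(long$enzyme)]
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time / 60, y = .data$flux,
                                     colour = .data$enzyme)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time after perturbation (min)",
                  y = if (relative) "flux (relative to steady state)"
                      else "flux (uM/s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Indicator-versus-parameter scatter for a cohort
#'
#' @param table A `cohort_table`.
#' @param parameter Kinetic parameter on the x axis (default `vmax`).
#' @param indicator Indicator on the y axis (default `initial_ratio`).
#' @return A ggplot object.
#' @export
plot_indicator_scatter <- function(table, parameter = "vmax",
                                   indicator = "initial_ratio") {
  stopifnot(parameter %in% names(table), indicator %in% names(table))
  ggplot2::ggplot(tibble::as_tibble(table),
                  ggplot2::aes(x = .data[[parameter]],
                               y = .data[[indicator]])) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = parameter, y = indicator) +
    ggplot2::theme_minimal()
}

#' Heat-map view of a Vmax x KmG6P indicator surface
#'
#' @param grid Output of [vmax_km_grid()].
#' @param indicator One of `initial_ratio`, `recovery_time`,
#'   `amount_of_change`.
#' @return A ggplot object (non-recovered cells are shown as missing).
#' @export
plot_grid_surface <- function(grid, indicator = "initial_ratio") {
  stopifnot(indicator %in% names(grid))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$vmax, y = .data$km_g6p,
                                     fill = .data[[indicator]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Vmax", y = "KmG6P (uM)", fill = indicator) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
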