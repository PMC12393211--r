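# ggplot2 display helpers for trajectories, parameter sweeps, effective-
# offset maps and slope tables.

#' Plot a set of signal trajectories
#'
#' @param trajectories A named list of trajectory tibbles
#'   ([ase_trajectory()]); names label the curves (e.g. the Gy or k0y value).
#' @return A ggplot: signal versus nominal offset, one colored line per
#'   trajectory.
#' @examples
#' tis <- tissue_params(); ro <- epi_readout(v = 0.077)
#' tr <- lapply(c(`-50` = -50, `0` = 0, `50` = 50), function(g)
#'   ase_trajectory(tis, ro, field_state(Gy = g), tau = default_tau_grid(501)))
#' plot_trajectories(tr)
#' @export
plot_trajectories <- function(trajectories) {
  stopifnot(is.list(trajectories), !is.null(names(trajectories)))
  d <- dplyr::bind_rows(trajectories, .id = "curve")
  ggplot2::ggplot(d, ggplot2::aes(.data$tau, .data$signal,
                                  colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "nominal offset tau (ms)", y = "signal magnitude",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname sweep_qbold
#' @param object A `"qbold_sweep"` tibble.
#' @param ... Unused.
#' @return `autoplot()`: apparent parameters versus `gamma*Gy/v`, one panel
#'   per parameter, colored by `k0y`; closed-form predictions drawn dashed.
#' @export
autoplot.qbold_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object, .data$valid),
    c("r2prime_hat", "dbv_hat", "oef_hat"),
    names_to = "parameter", values_to = "estimate"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$gamma_gy_over_v, .data$estimate,
                                     colour = factor(.data$k0y))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "gamma*Gy/v", y = "apparent value",
                  colour = "k0y (rad/mm)") +
    ggplot2::theme_minimal()
}

#' @rdname estimate_tau_eff
#' @param object A `"tau_eff_map"`.
#' @param ... Unused.
#' @return `autoplot()`: raster of the effective-offset map (unreliable
#'   voxels blank).
#' @export
autoplot.tau_eff_map <- function(object, ...) {
  d <- as_tibble(object)
  d$tau_eff[!d$reliable] <- NA
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$tau_eff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "tau_eff (ms)") +
    ggplot2::theme_minimal()
}

#' @rdname slope_vs_tau_table
#' @param object A `"slope_table"` tibble.
#' @param ... Unused.
#' @return `autoplot()`: slope versus nominal offset with CI whiskers,
#'   one panel per regressor.
#' @export
autoplot.slope_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$tau, .data$slope)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 1) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~x_label, scales = "free_y") +
    ggplot2::labs(x = "nominal offset tau (ms)", y = "Theil-Sen slope") +
    ggplot2::theme_minimal()
}
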