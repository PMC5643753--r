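#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scaling-law fit
#'
#' Log-log plot of mean conduction velocity against the swept variable with
#' the fitted power law; a slope-1/2 line is the model's prediction.
#'
#' @param object A `scaling_fit` from [scaling_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  grid <- object$grid
  grid$fitted <- exp(object$intercept + object$slope * log(grid$value))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$value, y = .data$mean_velocity_um_per_ns)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_velocity_um_per_ns - .data$se_velocity,
      ymax = .data$mean_velocity_um_per_ns + .data$se_velocity
    )) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = if (object$variable == "density") {
        "channel density [channels/µm²]"
      } else {
        "axon diameter [µm]"
      },
      y = "mean conduction velocity [µm/ns]",
      title = sprintf(
        "slope %.3f ± %.3f (square-root law predicts 0.5)",
        object$slope, object$stderr_slope
      )
    )
}

#' Plot per-hop times of a conduction simulation
#'
#' Histogram of the hop times; in sampled geometry their spread reflects the
#' hop-angle distribution (hop time grows as the squared hop distance).
#'
#' @param object A `propagation_result` from [simulate_conduction()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.propagation_result <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object$hops, ggplot2::aes(x = .data$hop_time_ns)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(
      x = "hop time [ns]", y = "hops",
      title = sprintf(
        "%d hops, velocity %.3g m/s (%s geometry)",
        object$n_lines, object$conduction_velocity_m_per_s, object$geometry_mode
      )
    )
}

#' Plot the hop-distance distribution
#'
#' Density of sampled channel-to-channel distances at a given channel
#' density, with the ring spacing (lower bound), the `2/sqrt(3)` upper bound
#' and the closed-form mean marked.
#'
#' @param density_per_um2 Channel density (channels/um^2).
#' @param n Number of sampled hops.
#' @param seed Optional RNG seed.
#' @return A ggplot.
#' @export
plot_hop_distances <- function(density_per_um2, n = 1e5, seed = NULL) {
  d <- hop_distance(sample_theta(n, seed = seed), density_per_um2)
  s <- line_spacing(density_per_um2)
  ggplot2::ggplot(tibble(r_um = d), ggplot2::aes(x = .data$r_um)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = s, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 2 / sqrt(3) * s, linetype = "dashed") +
    ggplot2::geom_vline(
      xintercept = mean_hop_distance_closed(density_per_um2),
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "hop distance [µm]", y = "hops",
      title = sprintf("hop distances at Cd = %g channels/µm²", density_per_um2)
    )
}
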