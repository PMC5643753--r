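#' Tidy a conduction simulation
#'
#' `tidy()` returns the per-hop records (one row per ring-to-ring
#' transition); `glance()` returns a one-row summary.
#'
#' @param x A `propagation_result` from [simulate_conduction()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.propagation_result <- function(x, ...) {
  x$hops
}

#' @rdname tidy.propagation_result
#' @export
glance.propagation_result <- function(x, ...) {
  tibble(
    density_per_um2 = x$density_per_um2,
    diameter_um = x$diameter_um,
    n_lines = x$n_lines,
    span_um = x$span_um,
    total_time_ns = x$total_time_ns,
    conduction_velocity_um_per_ns = x$conduction_velocity_um_per_ns,
    conduction_velocity_m_per_s = x$conduction_velocity_m_per_s,
    geometry_mode = x$geometry_mode,
    force_mode = x$force_mode,
    seed = x$seed
  )
}

#' Tidy a scaling-law fit
#'
#' `tidy()` returns the regression terms of the log-log fit; `glance()`
#' returns the one-row fit summary (slope, its standard error, r^2, sweep
#' settings).
#'
#' @param x A `scaling_fit` from [scaling_sweep()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", paste0("log(", x$variable, ")")),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$stderr_slope)
  )
}

#' @rdname tidy.scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(
    variable = x$variable,
    slope = x$slope,
    stderr_slope = x$stderr_slope,
    r_squared = x$r_squared,
    n_grid = nrow(x$grid),
    reps = x$reps,
    length_um = x$length_um,
    geometry_mode = x$geometry_mode,
    force_mode = x$force_mode,
    seed = x$seed
  )
}
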