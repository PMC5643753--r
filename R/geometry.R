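#' Cylindrical axon geometry
#'
#' Describes an unmyelinated axon as a cylinder of diameter `diameter_um` and
#' length `length_um` and carries the derived cross-sectional and membrane
#' quantities used throughout the package. Diameters of unmyelinated axons
#' typically fall in 0.2--1.2 um; values outside that range are accepted with
#' a warning.
#'
#' @param diameter_um Axon diameter in micrometres. Must be positive.
#' @param length_um Axon length in micrometres. Must be positive.
#'
#' @return An object of class `axon_geometry`: a list with `diameter_um`,
#'   `length_um`, `circumference_um` (pi D), `cross_section_area_um2`
#'   (pi D^2 / 4), `membrane_area_um2` (pi D L) and `volume_um3`
#'   (pi D^2 L / 4).
#'
#' @examples
#' ax <- axon_geometry(diameter_um = 1, length_um = 10)
#' ax$membrane_area_um2  # pi * 10
#' @export
axon_geometry <- function(diameter_um, length_um) {
  if (!is.numeric(diameter_um) || length(diameter_um) != 1 || !is.finite(diameter_um) ||
      diameter_um <= 0) {
    abort("`diameter_um` must be a single positive number.")
  }
  if (!is.numeric(length_um) || length(length_um) != 1 || !is.finite(length_um) ||
      length_um <= 0) {
    abort("`length_um` must be a single positive number.")
  }
  if (diameter_um < 0.2 || diameter_um > 1.2) {
    warn(sprintf(
      "diameter_um = %g is outside the 0.2-1.2 um range typical of unmyelinated axons.",
      diameter_um
    ))
  }
  structure(
    list(
      diameter_um = diameter_um,
      length_um = length_um,
      circumference_um = pi * diameter_um,
      cross_section_area_um2 = pi * diameter_um^2 / 4,
      membrane_area_um2 = pi * diameter_um * length_um,
      volume_um3 = pi * diameter_um^2 * length_um / 4
    ),
    class = "axon_geometry"
  )
}

#' @export
print.axon_geometry <- function(x, ...) {
  cat("<axon_geometry>\n")
  cat(sprintf("  diameter: %g um, length: %g um\n", x$diameter_um, x$length_um))
  cat(sprintf(
    "  membrane area: %g um^2, intracellular volume: %g um^3\n",
    x$membrane_area_um2, x$volume_um3
  ))
  invisible(x)
}

as_diameter <- function(axon) {
  if (inherits(axon, "axon_geometry")) {
    axon$diameter_um
  } else if (is.numeric(axon) && length(axon) == 1 && is.finite(axon) && axon > 0) {
    axon
  } else {
    abort("`axon` must be an `axon_geometry` object or a single positive diameter in um.")
  }
}

check_density <- function(density_per_um2, warn_range = TRUE) {
  if (!is.numeric(density_per_um2) || any(!is.finite(density_per_um2)) ||
      any(density_per_um2 <= 0)) {
    abort("channel density must be positive (channels/um^2).")
  }
  if (warn_range && any(density_per_um2 < 5 | density_per_um2 > 50)) {
    warn("channel density outside the 5-50 channels/um^2 range reported for unmyelinated axons.")
  }
  invisible(density_per_um2)
}

#' NaV channel lattice on a cylindrical axon
#'
#' The model places voltage-gated sodium (NaV) channels on rings ("channel
#' lines") around the axon: with surface density `density_per_um2` the rings
#' are `1/sqrt(density)` um apart and each ring carries `pi * D * sqrt(density)`
#' channels, so that channel count times the central angle between neighbours
#' closes the ring at exactly `2*pi`.
#'
#' @param density_per_um2 NaV channel surface density (channels/um^2).
#'   Densities outside 5--50 raise a warning.
#' @param axon An [axon_geometry()] object.
#'
#' @return An object of class `channel_lattice` with the density, the axon,
#'   `line_spacing_um`, `channels_per_line_real`, `channels_per_line`
#'   (floor, minimum 1) and `central_angle_rad`.
#' @examples
#' lat <- channel_lattice(25, axon_geometry(1, 1000))
#' lat$line_spacing_um  # 0.2
#' @export
channel_lattice <- function(density_per_um2, axon) {
  check_density(density_per_um2)
  if (!inherits(axon, "axon_geometry")) abort("`axon` must be an `axon_geometry`.")
  cpl <- channels_per_line(axon, density_per_um2)
  structure(
    list(
      density_per_um2 = density_per_um2,
      axon = axon,
      line_spacing_um = line_spacing(density_per_um2),
      channels_per_line_real = cpl$real,
      channels_per_line = cpl$realized,
      central_angle_rad = central_angle(axon, density_per_um2)
    ),
    class = "channel_lattice"
  )
}

#' @export
print.channel_lattice <- function(x, ...) {
  cat("<channel_lattice>\n")
  cat(sprintf(
    "  density: %g channels/um^2 on D = %g um axon\n",
    x$density_per_um2, x$axon$diameter_um
  ))
  cat(sprintf(
    "  ring spacing: %g um; %g channels/ring (central angle %g rad)\n",
    x$line_spacing_um, x$channels_per_line_real, x$central_angle_rad
  ))
  invisible(x)
}

#' Spacing between adjacent NaV channel rings
#'
#' With `density_per_um2` channels per um^2 arranged on evenly spaced rings,
#' adjacent rings are `density^(-1/2)` um apart.
#'
#' @param density_per_um2 Channel density (channels/um^2); vectorized.
#' @return Ring spacing in um.
#' @examples
#' line_spacing(25)  # 0.2
#' @export
line_spacing <- function(density_per_um2) {
  check_density(density_per_um2, warn_range = FALSE)
  density_per_um2^(-1 / 2)
}

#' Channels on one ring
#'
#' The ring at one cross-section carries `pi * D * sqrt(density)` channels
#' (circumference divided by the in-ring spacing `1/sqrt(density)`). The
#' expectation-level value is real; the integer realization is the floor,
#' with a minimum of one channel per ring.
#'
#' @param axon An [axon_geometry()] or a diameter in um.
#' @param density_per_um2 Channel density (channels/um^2).
#' @return A list with `real` and `realized` counts.
#' @examples
#' channels_per_line(axon_geometry(1, 1), 25)$real  # pi * 5
#' @export
channels_per_line <- function(axon, density_per_um2) {
  d <- as_diameter(axon)
  check_density(density_per_um2, warn_range = FALSE)
  real <- pi * d * sqrt(density_per_um2)
  list(real = real, realized = pmax(1, floor(real)))
}

#' Central angle between adjacent channels on a ring
#'
#' @inheritParams channels_per_line
#' @return Angle in radians, `2 / (D * sqrt(density))`.
#' @examples
#' central_angle(1, 25)  # 0.4
#' @export
central_angle <- function(axon, density_per_um2) {
  d <- as_diameter(axon)
  check_density(density_per_um2, warn_range = FALSE)
  2 / (d * sqrt(density_per_um2))
}

#' Sample hop angles
#'
#' The angle between the axon's longitudinal line and the line joining a NaV
#' channel to the next channel on the next ring is uniform on
#' `[-pi/6, pi/6)` (constant density 3/pi).
#'
#' @param n Number of draws (>= 1).
#' @param seed Optional RNG seed for a reproducible draw; the global RNG
#'   state is left untouched when a seed is given.
#' @return Numeric vector of n angles in radians.
#' @export
sample_theta <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1) {
    abort("`n` must be a single integer >= 1.")
  }
  n <- as.integer(n)
  draw <- function() runif(n, min = -pi / 6, max = pi / 6)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Distance to the next channel at a given hop angle
#'
#' A hop at angle `theta` from the longitudinal line crosses one ring spacing
#' longitudinally, so the channel-to-channel distance is
#' `(sqrt(density) * cos(theta))^(-1)`. The distance lies between the ring
#' spacing (theta = 0) and `2/sqrt(3)` times it (theta at the sector edge).
#'
#' @param theta_rad Hop angle(s) in radians, each in `[-pi/6, pi/6)`.
#' @param density_per_um2 Channel density (channels/um^2).
#' @return Hop distance(s) in um.
#' @examples
#' hop_distance(0, 25)  # 0.2, the ring spacing
#' @export
hop_distance <- function(theta_rad, density_per_um2) {
  if (!is.numeric(theta_rad) || any(!is.finite(theta_rad)) ||
      any(theta_rad < -pi / 6 | theta_rad >= pi / 6)) {
    abort("`theta_rad` must lie in [-pi/6, pi/6).")
  }
  check_density(density_per_um2, warn_range = FALSE)
  1 / (sqrt(density_per_um2) * cos(theta_rad))
}

#' Mean hop distance, closed form
#'
#' The average channel-to-channel distance over the uniform hop-angle
#' distribution is the integral of `(sqrt(Cd) * cos(pi x / 6))^(-1)` over
#' `x` in (0, 1), which evaluates to `(3 ln 3) / pi * Cd^(-1/2)`
#' (about `1.0492 * Cd^(-1/2)`). See [reported_mean_hop_constant()] for the
#' differing constant reported in the original publication of this model.
#'
#' @param density_per_um2 Channel density (channels/um^2); vectorized.
#' @return Mean hop distance in um.
#' @examples
#' mean_hop_distance_closed(1)  # 3*log(3)/pi
#' @export
mean_hop_distance_closed <- function(density_per_um2) {
  check_density(density_per_um2, warn_range = FALSE)
  (3 * log(3) / pi) / sqrt(density_per_um2)
}

#' Mean hop-distance constant as originally reported
#'
#' The publication introducing this model reports the mean hop distance as
#' `pi * ln 3 / 12 * Cd^(-1/2)` (about `0.2875 * Cd^(-1/2)`). That constant
#' cannot be correct: the mean hop distance can never be smaller than the
#' ring spacing `Cd^(-1/2)` itself, and the substitution step that produced
#' it multiplies by `pi/6` where the change of variables requires `6/pi`.
#' The correctly evaluated integral gives `(3 ln 3)/pi` (see
#' [mean_hop_distance_closed()]); every downstream conclusion depends only on
#' the `Cd^(-1/2)` proportionality, which both constants share. This accessor
#' exposes the reported constant for comparison.
#'
#' @return The dimensionless constant `pi * log(3) / 12`.
#' @export
reported_mean_hop_constant <- function() {
  pi * log(3) / 12
}

#' Mean hop distance by Monte Carlo
#'
#' Estimates the mean channel-to-channel distance by sampling hop angles and
#' averaging [hop_distance()]; the independent stochastic check on
#' [mean_hop_distance_closed()].
#'
#' @param density_per_um2 Channel density (channels/um^2).
#' @param n Number of draws (>= 100).
#' @param seed Optional RNG seed (reproducible draw, global state untouched).
#' @return A one-row tibble with `estimate` (um), `se`, `n_draws`, `seed`.
#' @export
mean_hop_distance_mc <- function(density_per_um2, n = 1e6, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 100) {
    abort("`n` must be >= 100 for a meaningful Monte-Carlo standard error.")
  }
  check_density(density_per_um2, warn_range = FALSE)
  d <- hop_distance(sample_theta(n, seed = seed), density_per_um2)
  tibble(
    estimate = mean(d),
    se = sd(d) / sqrt(length(d)),
    n_draws = as.integer(n),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

#' Mean hop distance by the defining Riemann sum
#'
#' The discrete average `(1/n) * sum_{k=1..n} (sqrt(Cd) * cos(k pi/(6 n)))^(-1)`
#' whose n -> Inf limit defines the mean hop distance. A right-endpoint sum of
#' an increasing integrand, so it decreases monotonically onto the closed form.
#'
#' @param density_per_um2 Channel density (channels/um^2).
#' @param n Number of subdivisions (>= 1).
#' @return The discrete average in um.
#' @examples
#' mean_hop_distance_riemann(1, 1)  # 2/sqrt(3), the single k = n term
#' @export
mean_hop_distance_riemann <- function(density_per_um2, n) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1) {
    abort("`n` must be a single integer >= 1.")
  }
  check_density(density_per_um2, warn_range = FALSE)
  k <- seq_len(n)
  mean(1 / (sqrt(density_per_um2) * cos(k * pi / (6 * n))))
}

#' Number of channel rings along an axon length
#'
#' Rings are `1/sqrt(Cd)` um apart, so a length `L` um spans `L * sqrt(Cd)`
#' rings in expectation; the event-count realization is the floor (minimum 1).
#'
#' @param length_um Axon length in um.
#' @param density_per_um2 Channel density (channels/um^2).
#' @return A list with `real` and `realized` counts.
#' @examples
#' channel_lines_along(1e5, 5)$real  # 1e5 * sqrt(5)
#' @export
channel_lines_along <- function(length_um, density_per_um2) {
  if (!is.numeric(length_um) || any(!is.finite(length_um)) || any(length_um <= 0)) {
    abort("`length_um` must be positive.")
  }
  check_density(density_per_um2, warn_range = FALSE)
  real <- length_um * sqrt(density_per_um2)
  list(real = real, realized = pmax(1, floor(real)))
}

#' Tabulate lattice geometry over channel densities
#'
#' One row per density: ring spacing, channels per ring, central angle and
#' mean hop distance, for export or plotting.
#'
#' @param density_per_um2 Vector of channel densities (channels/um^2).
#' @param diameter_um Axon diameter in um (default 0.6, mid-range).
#' @return A tibble with columns `density_per_um2`, `line_spacing_um`,
#'   `channels_per_line`, `central_angle_rad`, `mean_hop_distance_um`.
#' @examples
#' geometry_table(c(5, 25, 50))
#' @export
geometry_table <- function(density_per_um2, diameter_um = 0.6) {
  check_density(density_per_um2, warn_range = FALSE)
  tibble(
    density_per_um2 = density_per_um2,
    line_spacing_um = line_spacing(density_per_um2),
    channels_per_line = pi * diameter_um * sqrt(density_per_um2),
    central_angle_rad = central_angle(diameter_um, density_per_um2),
    mean_hop_distance_um = mean_hop_distance_closed(density_per_um2)
  )
}
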