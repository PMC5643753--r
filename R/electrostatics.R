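#' Sodium influx through one open NaV channel
#'
#' Within the first microsecond after a NaV channel opens, electrostatic
#' repulsion between the already-entered and the still-entering sodium ions is
#' negligible, so the charge inflow rate is treated as a constant `Q1`
#' coulombs per nanosecond. The default charge unit is reduced (elementary
#' charge 1) so the model's proportionalities read off directly; pass
#' `elementary_charge = 1.602e-19` for SI charges.
#'
#' @param q1_per_ns Charge inflow rate Q1 (charge units per ns), > 0.
#' @param elementary_charge Charge carried by one monovalent ion (default 1,
#'   reduced units; physically 1.602e-19 C).
#' @return An object of class `channel_inflow`.
#' @export
channel_inflow <- function(q1_per_ns = 1, elementary_charge = 1) {
  if (!is.numeric(q1_per_ns) || length(q1_per_ns) != 1 || q1_per_ns <= 0) {
    abort("`q1_per_ns` must be a single positive number.")
  }
  if (!is.numeric(elementary_charge) || length(elementary_charge) != 1 ||
      elementary_charge <= 0) {
    abort("`elementary_charge` must be a single positive number.")
  }
  structure(
    list(q1_per_ns = q1_per_ns, elementary_charge = elementary_charge),
    class = "channel_inflow"
  )
}

#' Coulomb-force field parameters
#'
#' The model applies the bare Coulomb force between the inflowing sodium
#' mass and nearby ions. By default the Coulomb constant is 1 (reduced
#' units), matching the constant-free force proportionalities of the model;
#' `physical = TRUE` switches to `1/(4 pi eps0 eps_r)` with relative
#' permittivity 80 (water) as a documented extension.
#'
#' @param coulomb_constant Force scale k (default 1, reduced units). Ignored
#'   when `physical = TRUE`.
#' @param relative_permittivity Dimensionless, default 80 (water).
#' @param physical If TRUE, use k = 1/(4 pi eps0 eps_r) in SI units.
#' @return An object of class `coulomb_field`.
#' @export
coulomb_field <- function(coulomb_constant = 1, relative_permittivity = 80,
                          physical = FALSE) {
  eps0 <- 8.8541878128e-12
  k <- if (isTRUE(physical)) {
    1 / (4 * pi * eps0 * relative_permittivity)
  } else {
    coulomb_constant
  }
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("the Coulomb constant must be a single positive number.")
  }
  structure(
    list(
      coulomb_constant = k,
      relative_permittivity = relative_permittivity,
      physical = isTRUE(physical)
    ),
    class = "coulomb_field"
  )
}

#' Ionic transport parameters
#'
#' Carries the molar mobility omega and ionic concentration C of the
#' flux law J = omega * C * F (F the driving force per gram-ion), from which
#' the migration velocity is omega * F = J / C.
#'
#' @param molar_mobility Molar mobility omega (model units), >= 0.
#' @param concentration Ionic concentration C (model units), >= 0.
#' @return An object of class `ionic_transport`.
#' @export
ionic_transport <- function(molar_mobility, concentration) {
  if (!is.numeric(molar_mobility) || length(molar_mobility) != 1 || molar_mobility < 0) {
    abort("`molar_mobility` must be a single non-negative number.")
  }
  if (!is.numeric(concentration) || length(concentration) != 1 || concentration < 0) {
    abort("`concentration` must be a single non-negative number.")
  }
  structure(
    list(molar_mobility = molar_mobility, concentration = concentration),
    class = "ionic_transport"
  )
}

VALIDITY_WINDOW_NS <- 1e3

check_window <- function(t_ns) {
  if (any(!is.finite(t_ns)) || any(t_ns < 0) || any(t_ns > VALIDITY_WINDOW_NS)) {
    abort(paste0(
      "time must lie in [0, 1000] ns: the constant-inflow approximation ",
      "holds only within the first 1.0 us after channel opening."
    ))
  }
  invisible(t_ns)
}

#' Charge passed through an open channel
#'
#' At constant inflow rate the charge after `t` ns is `Q1 * t`. Only valid
#' inside the 1.0 us constant-rate window.
#'
#' @param inflow A [channel_inflow()].
#' @param t_ns Elapsed time(s) since channel opening, 0 <= t <= 1000 ns.
#' @return Charge(s) in the inflow's charge unit.
#' @export
charge_through_channel <- function(inflow, t_ns) {
  stopifnot(inherits(inflow, "channel_inflow"))
  check_window(t_ns)
  inflow$q1_per_ns * t_ns
}

#' Coulomb force on an ion near the next channel
#'
#' The inflowing sodium mass (charge `Q1 * t`) exerts on a monovalent ion at
#' distance `r` a force of magnitude `k * Q1 * t * e / r^2`: repulsive
#' (positive) for cations, attractive (negative) for anions, identical in
#' magnitude. Linear in `t`, inverse-square in `r`.
#'
#' @param inflow A [channel_inflow()].
#' @param t_ns Elapsed time(s) in ns, inside the 1.0 us validity window.
#' @param r Distance(s) from the inflow point, > 0 (um in the lattice model).
#' @param field A [coulomb_field()].
#' @param species `"cation"` or `"anion"`; sets the sign.
#' @return Signed force(s) in model units.
#' @export
coulomb_force <- function(inflow, t_ns, r, field = coulomb_field(),
                          species = c("cation", "anion")) {
  stopifnot(inherits(inflow, "channel_inflow"), inherits(field, "coulomb_field"))
  species <- match.arg(species)
  check_window(t_ns)
  if (any(!is.finite(r)) || any(r <= 0)) abort("`r` must be positive.")
  mag <- field$coulomb_constant * inflow$q1_per_ns * t_ns *
    inflow$elementary_charge / r^2
  if (species == "cation") mag else -mag
}

#' Ionic migration velocity and flux
#'
#' Flux `J = omega * C * drive` and migration velocity `omega * drive`;
#' velocity equals `J / C` whenever the concentration is positive.
#'
#' @param transport An [ionic_transport()].
#' @param drive Driving force per gram-ion (model units).
#' @return `migration_velocity()`: velocity; `ion_flux()`: flux.
#' @export
migration_velocity <- function(transport, drive) {
  stopifnot(inherits(transport, "ionic_transport"))
  transport$molar_mobility * drive
}

#' @rdname migration_velocity
#' @export
ion_flux <- function(transport, drive) {
  stopifnot(inherits(transport, "ionic_transport"))
  transport$molar_mobility * transport$concentration * drive
}

#' Hop-timing parameters
#'
#' The next NaV channel opens when the Coulomb force on the ions around it
#' reaches `threshold_force`. In `"nearest_line"` mode only the adjacent
#' opened ring contributes force; in `"superposed"` mode the force is
#' multiplied by the inverse-square sum over all previously opened rings
#' ([superposition_factor()]), which can only shorten hop times.
#'
#' @param threshold_force Minimum Coulomb force that triggers the next
#'   channel, > 0 (model units).
#' @param mode `"nearest_line"` (default) or `"superposed"`.
#' @param n_lines Number of contributing upstream rings in superposed mode;
#'   `Inf` (default) uses the full pi^2/6 factor.
#' @param reference_time_ns Optional t0 calibration record (ns).
#' @return An object of class `hop_timing`.
#' @export
hop_timing <- function(threshold_force = 1, mode = c("nearest_line", "superposed"),
                       n_lines = Inf, reference_time_ns = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold_force) || length(threshold_force) != 1 ||
      threshold_force <= 0) {
    abort("`threshold_force` must be a single positive number.")
  }
  structure(
    list(
      threshold_force = threshold_force,
      mode = mode,
      n_lines = n_lines,
      reference_time_ns = reference_time_ns
    ),
    class = "hop_timing"
  )
}

#' Multi-ring force superposition factor
#'
#' Opened rings at 1, 2, 3, ... ring spacings behind the wavefront contribute
#' Coulomb force in the ratio 1, 1/4, 1/9, ...; the total relative to the
#' nearest ring alone is the partial sum of `sum 1/k^2`, which increases
#' monotonically to `pi^2/6` (Basel sum) as the number of rings grows.
#'
#' @param n_lines Number of contributing rings (>= 1), or `Inf` for the full
#'   factor `pi^2/6`.
#' @return Dimensionless factor in `[1, pi^2/6]`.
#' @examples
#' superposition_factor(2)    # 1.25
#' superposition_factor(Inf)  # pi^2 / 6
#' @export
superposition_factor <- function(n_lines = Inf) {
  if (!is.numeric(n_lines) || length(n_lines) != 1 || is.na(n_lines) || n_lines < 1) {
    abort("`n_lines` must be a single value >= 1 (or Inf).")
  }
  if (is.infinite(n_lines)) {
    return(pi^2 / 6)
  }
  sum(1 / seq_len(floor(n_lines))^2)
}

#' Time for the Coulomb force to trigger the next channel
#'
#' With the force growing linearly in time, the threshold is crossed at
#' `t = threshold_force * r^2 / (k * Q1 * e * S)`, where `S` is the
#' superposition factor of the timing mode (1 in nearest-line mode). The hop
#' time grows as the square of `r`, so at the nominal spacing `Cd^(-1/2)` it scales
#' as `1/Cd`. A solution outside the 1.0 us constant-inflow window is a model
#' breakdown and raises an error.
#'
#' @param r Hop distance(s), > 0 (um in the lattice model).
#' @param timing A [hop_timing()].
#' @param inflow A [channel_inflow()].
#' @param field A [coulomb_field()].
#' @return Hop time(s) in ns.
#' @examples
#' hop_time(1)  # 1 with unit parameters
#' @export
hop_time <- function(r, timing = hop_timing(), inflow = channel_inflow(),
                     field = coulomb_field()) {
  stopifnot(
    inherits(timing, "hop_timing"),
    inherits(inflow, "channel_inflow"),
    inherits(field, "coulomb_field")
  )
  if (any(!is.finite(r)) || any(r <= 0)) abort("`r` must be positive.")
  s_fac <- if (timing$mode == "superposed") superposition_factor(timing$n_lines) else 1
  t <- timing$threshold_force * r^2 /
    (field$coulomb_constant * inflow$q1_per_ns * inflow$elementary_charge * s_fac)
  if (any(t > VALIDITY_WINDOW_NS)) {
    abort(paste0(
      "model breakdown: a hop time exceeds the 1.0 us window in which the ",
      "sodium inflow rate can be treated as constant; the threshold crossing ",
      "must complete well inside 1 us."
    ))
  }
  t
}
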