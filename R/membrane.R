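#' Ionic milieu across the axon membrane
#'
#' Concentrations (mEq/l, equal to mmol/l for the monovalent ions modelled
#' here) and relative permeabilities of K+, Na+ and Cl- on both sides of the
#' membrane, plus the physical constants of the GHK voltage equation.
#' Defaults are the textbook mammalian resting milieu with intracellular
#' Na+ 15 and K+ 140 mEq/l, at body temperature.
#'
#' @param conc_in,conc_out Named numeric vectors with entries `K`, `Na`, `Cl`
#'   (mEq/l), all >= 0.
#' @param permeability Named numeric vector with relative permeabilities
#'   `K`, `Na`, `Cl` (dimensionless, >= 0, at least one positive).
#' @param temperature_K Absolute temperature (default 310.15 K).
#' @param faraday Faraday constant (C/mol).
#' @param gas_constant Ideal gas constant (J/(mol K)).
#' @return An object of class `membrane_milieu`.
#' @export
membrane_milieu <- function(conc_in = c(K = 140, Na = 15, Cl = 10),
                            conc_out = c(K = 5, Na = 145, Cl = 110),
                            permeability = c(K = 1, Na = 0.04, Cl = 0.45),
                            temperature_K = 310.15,
                            faraday = 96485.332,
                            gas_constant = 8.314463) {
  need <- c("K", "Na", "Cl")
  for (nm in c("conc_in", "conc_out", "permeability")) {
    v <- get(nm)
    if (!is.numeric(v) || !all(need %in% names(v)) || any(v[need] < 0)) {
      abort(sprintf("`%s` must be a named non-negative vector with entries K, Na, Cl.", nm))
    }
  }
  if (all(permeability[need] == 0)) {
    abort("at least one permeability must be positive.")
  }
  if (temperature_K <= 0) abort("`temperature_K` must be positive.")
  structure(
    list(
      conc_in = conc_in[need], conc_out = conc_out[need],
      permeability = permeability[need],
      temperature_K = temperature_K,
      faraday = faraday, gas_constant = gas_constant
    ),
    class = "membrane_milieu"
  )
}

#' Goldman-Hodgkin-Katz membrane potential
#'
#' Steady-state membrane potential from permeability-weighted ion
#' concentrations:
#' `E = (RT/F) ln[(P_K [K]out + P_Na [Na]out + P_Cl [Cl]in) /
#'               (P_K [K]in + P_Na [Na]in + P_Cl [Cl]out)]`.
#' The chloride terms swap sides relative to the cations — the standard GHK
#' convention for a monovalent anion. When only one permeability is nonzero
#' the expression reduces to that ion's Nernst potential.
#'
#' @param milieu A [membrane_milieu()].
#' @param unit `"mV"` (default) or `"V"`.
#' @return The membrane potential (single number).
#' @examples
#' ghk_voltage(membrane_milieu())  # about -67 mV
#' @export
ghk_voltage <- function(milieu, unit = c("mV", "V")) {
  stopifnot(inherits(milieu, "membrane_milieu"))
  unit <- match.arg(unit)
  p <- milieu$permeability
  ci <- milieu$conc_in
  co <- milieu$conc_out
  num <- p[["K"]] * co[["K"]] + p[["Na"]] * co[["Na"]] + p[["Cl"]] * ci[["Cl"]]
  den <- p[["K"]] * ci[["K"]] + p[["Na"]] * ci[["Na"]] + p[["Cl"]] * co[["Cl"]]
  if (num <= 0) {
    abort("GHK numerator (P_K[K]out + P_Na[Na]out + P_Cl[Cl]in) is not positive.")
  }
  if (den <= 0) {
    abort("GHK denominator (P_K[K]in + P_Na[Na]in + P_Cl[Cl]out) is not positive.")
  }
  volts <- (milieu$gas_constant * milieu$temperature_K / milieu$faraday) * log(num / den)
  if (unit == "mV") volts * 1e3 else volts
}

#' Membrane charge-budget constants
#'
#' Constants needed to count ions moved per action potential: membrane
#' capacitance per um^2 (1.0 uF/cm^2 = 1e-14 C/(V um^2)), the action-potential
#' amplitude (100 mV), the elementary charge and the Avogadro constant.
#'
#' @param capacitance_per_um2 Membrane capacitance, C/(V um^2). Default 1e-14.
#' @param delta_v Action-potential amplitude in volts. Default 0.1.
#' @param elementary_charge Elementary charge in C. Default 1.602e-19.
#' @param avogadro Avogadro constant, 1/mol. Default 6.02e23.
#' @return An object of class `charge_budget`.
#' @export
charge_budget <- function(capacitance_per_um2 = 1e-14, delta_v = 0.1,
                          elementary_charge = 1.602e-19, avogadro = 6.02e23) {
  vals <- c(capacitance_per_um2, delta_v, elementary_charge, avogadro)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all charge-budget fields must be strictly positive.")
  }
  structure(
    list(
      capacitance_per_um2 = capacitance_per_um2, delta_v = delta_v,
      elementary_charge = elementary_charge, avogadro = avogadro
    ),
    class = "charge_budget"
  )
}

#' Capacitance unit conversion
#'
#' Converts a membrane capacitance from uF/cm^2 to C/(V um^2):
#' 1 uF/cm^2 = 1e-6 C/V over 1e8 um^2 = 1e-14 C/(V um^2).
#'
#' @param value_uF_per_cm2 Capacitance in uF/cm^2, >= 0; vectorized.
#' @return Capacitance in C/(V um^2).
#' @examples
#' capacitance_unit_conversion(1.0)  # 1e-14
#' @export
capacitance_unit_conversion <- function(value_uF_per_cm2) {
  if (!is.numeric(value_uF_per_cm2) || any(value_uF_per_cm2 < 0)) {
    abort("`value_uF_per_cm2` must be non-negative.")
  }
  value_uF_per_cm2 * 1e-14
}

#' Sodium ions transferred per action potential
#'
#' Charging the membrane area `pi D L` um^2 by the action-potential amplitude
#' requires `C_m * dV * pi D L` coulombs, i.e.
#' `C_m * dV * pi D L / e` monovalent ions — with the default constants,
#' `pi D L / 1.602e-4` particles.
#'
#' @param axon An [axon_geometry()].
#' @param budget A [charge_budget()].
#' @return Ion particle count (real-valued).
#' @examples
#' transferred_ions(axon_geometry(1, 1))  # pi / 1.602e-4
#' @export
transferred_ions <- function(axon, budget = charge_budget()) {
  stopifnot(inherits(axon, "axon_geometry"), inherits(budget, "charge_budget"))
  budget$capacitance_per_um2 * budget$delta_v * axon$membrane_area_um2 /
    budget$elementary_charge
}

#' Intracellular cation count before sodium influx
#'
#' The cations (Na+ plus K+, 155 mEq/l by default) already inside the axon
#' volume `pi D^2 L / 4` um^3: `conc * 1e-3 mol/l * N_A * volume * 1e-15 l`.
#' With defaults the coefficient of `pi D^2 L` is 2.33e7 (3 s.f.).
#'
#' @param axon An [axon_geometry()].
#' @param budget A [charge_budget()] (supplies the Avogadro constant).
#' @param total_cation_conc Total intracellular cation concentration, mEq/l.
#'   Default 155 (Na 15 + K 140).
#' @return Cation particle count (real-valued).
#' @export
intracellular_cations <- function(axon, budget = charge_budget(),
                                  total_cation_conc = 155) {
  stopifnot(inherits(axon, "axon_geometry"), inherits(budget, "charge_budget"))
  if (total_cation_conc <= 0) abort("`total_cation_conc` must be positive.")
  total_cation_conc * 1e-3 * budget$avogadro * axon$volume_um3 * 1e-15
}

#' Intracellular cations per inflowing sodium ion
#'
#' The ratio [intracellular_cations()] / [transferred_ions()]; the axon
#' length cancels, leaving about `3.73e3 * D` resident cations per inflowing
#' ion with the default constants. Because the ratio exceeds 1000 across
#' nearly the whole unmyelinated diameter range, a single action potential
#' barely perturbs the intracellular cation concentration — which is why the
#' model may treat the axoplasm composition as fixed and consider only
#' adjacent-ring Coulomb interactions.
#'
#' @inheritParams intracellular_cations
#' @return Dimensionless ratio (cations per inflowing ion).
#' @examples
#' influx_ratio(axon_geometry(1, 1))  # about 3.7e3
#' @export
influx_ratio <- function(axon, budget = charge_budget(), total_cation_conc = 155) {
  intracellular_cations(axon, budget, total_cation_conc) /
    transferred_ions(axon, budget)
}

#' Conduction feasibility scenario
#'
#' The worked scenario behind the per-channel time budget: a 10 cm axon,
#' the low end of the NaV density range, and the 1 m/s conduction velocity
#' typical of an average-calibre unmyelinated fibre.
#'
#' @param axon_length_um Axon length in um (default 1e5 = 10 cm).
#' @param conduction_velocity_um_per_s Conduction velocity in um/s
#'   (default 1e6 = 1 m/s).
#' @param density_per_um2 NaV channel density (default 5 channels/um^2).
#' @return An object of class `feasibility_scenario`.
#' @export
feasibility_scenario <- function(axon_length_um = 1e5,
                                 conduction_velocity_um_per_s = 1e6,
                                 density_per_um2 = 5) {
  vals <- c(axon_length_um, conduction_velocity_um_per_s, density_per_um2)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all scenario fields must be strictly positive.")
  }
  structure(
    list(
      axon_length_um = axon_length_um,
      conduction_velocity_um_per_s = conduction_velocity_um_per_s,
      density_per_um2 = density_per_um2
    ),
    class = "feasibility_scenario"
  )
}

#' Per-channel time-budget feasibility report
#'
#' How much time conduction can spend at each NaV channel: the axon carries
#' `L * sqrt(Cd)` channels along a longitudinal line, the whole length is
#' crossed in `L / v` seconds, so each channel gets their quotient. Under the
#' default scenario that is about 4.5e-7 s — under a microsecond, far shorter
#' than action-potential generation itself, which is what motivates a
#' conduction mechanism that runs ahead of the action potential.
#'
#' @param scenario A [feasibility_scenario()].
#' @return A one-row tibble: `axon_length_um`, `density_per_um2`,
#'   `conduction_velocity_um_per_s`, `line_spacing_um`, `channels_per_line`,
#'   `total_travel_time_s`, `per_channel_time_s`, `within_budget`
#'   (TRUE when the per-channel time is below 1e-6 s).
#' @examples
#' feasibility_report()
#' @export
feasibility_report <- function(scenario = feasibility_scenario()) {
  stopifnot(inherits(scenario, "feasibility_scenario"))
  n_channels <- scenario$axon_length_um * sqrt(scenario$density_per_um2)
  total_s <- scenario$axon_length_um / scenario$conduction_velocity_um_per_s
  per_channel_s <- total_s / n_channels
  tibble(
    axon_length_um = scenario$axon_length_um,
    density_per_um2 = scenario$density_per_um2,
    conduction_velocity_um_per_s = scenario$conduction_velocity_um_per_s,
    line_spacing_um = line_spacing(scenario$density_per_um2),
    channels_per_line = n_channels,
    total_travel_time_s = total_s,
    per_channel_time_s = per_channel_s,
    within_budget = per_channel_s < 1e-6
  )
}
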