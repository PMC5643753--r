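# Reduced-unit building blocks shared across tests.

unit_inflow <- function() channel_inflow(q1_per_ns = 1, elementary_charge = 1)

unit_timing <- function(threshold = 1, mode = "nearest_line", n_lines = Inf) {
  hop_timing(threshold_force = threshold, mode = mode, n_lines = n_lines)
}

# A model with an explicit (uncalibrated) threshold so tests control the
# absolute time scale directly.
unit_model <- function(density_per_um2 = 25, geometry_mode = "sampled",
                       force_mode = "nearest_line", threshold = 1) {
  suppressWarnings(propagation_model(
    density_per_um2 = density_per_um2,
    geometry_mode = geometry_mode,
    force_mode = force_mode,
    threshold_force = threshold
  ))
}

# Quadrature oracle for E[sec^2(theta)], theta ~ U[-pi/6, pi/6).
e_sec2_oracle <- function() {
  (3 / pi) * stats::integrate(function(x) 1 / cos(x)^2, -pi / 6, pi / 6,
    rel.tol = 1e-12
  )$value
}
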