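test_that("density follows diameter linearly through the coupling constant", {
  expect_equal(density_from_diameter(1.2, alpha = 41.67), 50.0, tolerance = 1e-3)
  expect_equal(density_from_diameter(1.2), 50)
  expect_identical(density_from_diameter(1, alpha = 1), 1)
  expect_equal(density_from_diameter(0.8), 2 * density_from_diameter(0.4))
})

test_that("nominal-mode conduction is deterministic and equals the closed form", {
  mod <- unit_model(density_per_um2 = 25, geometry_mode = "nominal")
  s <- mod$lattice$line_spacing_um
  r1 <- simulate_conduction(mod, 100, seed = 1)
  r2 <- simulate_conduction(mod, 100, seed = 99)
  expect_identical(
    r1$conduction_velocity_um_per_ns,
    r2$conduction_velocity_um_per_ns
  )
  expect_equal(
    r1$conduction_velocity_um_per_ns,
    s / hop_time(s, mod$timing, mod$inflow, mod$field),
    tolerance = 1e-14
  )
  expect_equal(
    r1$conduction_velocity_um_per_ns,
    expected_velocity_closed(mod),
    tolerance = 1e-14
  )
})

test_that("identical (model, length, seed) reproduce a simulation bit-for-bit", {
  mod <- unit_model(density_per_um2 = 25)
  a <- simulate_conduction(mod, 200, seed = 31)
  b <- simulate_conduction(mod, 200, seed = 31)
  expect_identical(a$hops, b$hops)
  expect_identical(a$total_time_ns, b$total_time_ns)
})

test_that("sampled-mode mean hop time carries the E[sec^2 theta] factor", {
  e_sec2 <- e_sec2_oracle()
  expect_equal(e_sec2, 2 * sqrt(3) / pi, tolerance = 1e-12)

  mod <- unit_model(density_per_um2 = 25)
  res <- simulate_conduction(mod, 20000, seed = 77) # 1e5 hops
  t_nominal <- hop_time(
    mod$lattice$line_spacing_um,
    mod$timing, mod$inflow, mod$field
  )
  t_bar <- mean(res$hops$hop_time_ns)
  se <- sd(res$hops$hop_time_ns) / sqrt(nrow(res$hops))
  expect_lt(abs(t_bar - t_nominal * e_sec2), 3 * se)
})

test_that("mean simulated velocity matches the closed-form expectation within 3 SE", {
  for (cd in c(10, 25)) {
    mod <- unit_model(density_per_um2 = cd)
    v <- withr::with_seed(cd, vapply(
      1:50,
      function(i) simulate_conduction(mod, 400)$conduction_velocity_um_per_ns,
      numeric(1)
    ))
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - expected_velocity_closed(mod)), 3 * se)
  }
})

test_that("doubling channel density speeds conduction by sqrt(2)", {
  mod25 <- unit_model(density_per_um2 = 25)
  mod50 <- unit_model(density_per_um2 = 50)
  sim_mean <- function(mod, seed) {
    v <- withr::with_seed(seed, vapply(
      1:200,
      function(i) simulate_conduction(mod, 300)$conduction_velocity_um_per_ns,
      numeric(1)
    ))
    c(mean = mean(v), se = sd(v) / sqrt(length(v)))
  }
  a <- sim_mean(mod25, 1)
  b <- sim_mean(mod50, 2)
  ratio <- b[["mean"]] / a[["mean"]]
  se_ratio <- ratio * sqrt((a[["se"]] / a[["mean"]])^2 + (b[["se"]] / b[["mean"]])^2)
  expect_lt(abs(ratio - sqrt(2)), 3 * se_ratio)
})

test_that("closed-form velocity scales as sqrt(Cd) with the sec^2 geometry factor", {
  mod_n <- unit_model(density_per_um2 = 1, geometry_mode = "nominal")
  expect_identical(expected_velocity_closed(mod_n), 1)
  for (cd in c(5, 25)) {
    samp <- unit_model(density_per_um2 = cd)
    nom <- unit_model(density_per_um2 = cd, geometry_mode = "nominal")
    expect_equal(
      expected_velocity_closed(samp) / expected_velocity_closed(nom),
      pi / (2 * sqrt(3)),
      tolerance = 1e-12
    )
    expect_equal(
      expected_velocity_closed(unit_model(density_per_um2 = 4 * cd, geometry_mode = "nominal")),
      2 * expected_velocity_closed(nom),
      tolerance = 1e-12
    )
  }
})

test_that("calibration pins the reference velocity, doubles at 4x the diameter, idempotent", {
  mod <- propagation_model(diameter_um = 0.3)
  cal <- calibrate_reference(mod, target_velocity_m_per_s = 1, at_diameter_um = 0.3)
  at_ref <- suppressWarnings(propagation_model(
    diameter_um = 0.3,
    threshold_force = cal$timing$threshold_force
  ))
  expect_equal(expected_velocity_closed(at_ref) * 1e3, 1, tolerance = 1e-9)

  at_4ref <- suppressWarnings(propagation_model(
    diameter_um = 1.2,
    threshold_force = cal$timing$threshold_force
  ))
  expect_equal(expected_velocity_closed(at_4ref) * 1e3, 2, tolerance = 1e-9)

  twice <- calibrate_reference(cal, target_velocity_m_per_s = 1, at_diameter_um = 0.3)
  expect_equal(twice$timing$threshold_force, cal$timing$threshold_force, tolerance = 1e-12)
})

test_that("superposed force shortens every hop by pi^2/6 and leaves exponents alone", {
  thr <- 30
  near <- unit_model(density_per_um2 = 25, threshold = thr)
  sup <- unit_model(density_per_um2 = 25, force_mode = "superposed", threshold = thr)
  a <- simulate_conduction(near, 200, seed = 5)
  b <- simulate_conduction(sup, 200, seed = 5)
  expect_equal(
    a$hops$hop_time_ns / b$hops$hop_time_ns,
    rep(pi^2 / 6, nrow(a$hops)),
    tolerance = 1e-12
  )
  expect_equal(
    b$conduction_velocity_um_per_ns / a$conduction_velocity_um_per_ns,
    pi^2 / 6,
    tolerance = 1e-12
  )

  f_near <- scaling_sweep(near, "density", c(5, 10, 20, 50),
    reps = 30, length_um = 300, seed = 21
  )
  f_sup <- scaling_sweep(sup, "density", c(5, 10, 20, 50),
    reps = 30, length_um = 300, seed = 21
  )
  expect_lt(abs(f_near$slope - f_sup$slope), f_near$stderr_slope + f_sup$stderr_slope)
})

test_that("rescaling threshold and inflow together leaves results invariant", {
  a <- 13.7
  base <- unit_model(density_per_um2 = 25, threshold = 1)
  scaled <- suppressWarnings(propagation_model(
    density_per_um2 = 25, threshold_force = a,
    inflow = channel_inflow(q1_per_ns = a, elementary_charge = 1)
  ))
  ra <- simulate_conduction(base, 100, seed = 8)
  rb <- simulate_conduction(scaled, 100, seed = 8)
  expect_equal(ra$hops$hop_time_ns, rb$hops$hop_time_ns, tolerance = 1e-12)
})

test_that("hops that outlast the constant-inflow window abort the simulation", {
  slow <- unit_model(density_per_um2 = 25, threshold = 1e5)
  expect_error(simulate_conduction(slow, 10, seed = 1), "breakdown")
  expect_error(simulate_conduction(unit_model(), 1e-3), "at least one channel ring")
})

test_that("scaling sweeps recover the square-root law in both variables", {
  nom <- propagation_model(geometry_mode = "nominal")
  f <- scaling_sweep(nom, "density", c(5, 10, 20, 50), reps = 10, length_um = 200)
  expect_equal(f$slope, 0.5, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  samp <- propagation_model()
  fd <- scaling_sweep(samp, "density", c(5, 10, 20, 50),
    reps = 40, length_um = 400, seed = 14
  )
  expect_lt(abs(fd$slope - 0.5), 3 * fd$stderr_slope)
  fD <- scaling_sweep(samp, "diameter", c(0.2, 0.4, 0.8, 1.2),
    reps = 40, length_um = 400, seed = 15
  )
  expect_lt(abs(fD$slope - 0.5), 3 * fD$stderr_slope)

  expect_error(scaling_sweep(samp, "density", c(5, 10), reps = 40), "at least 4")
  expect_error(scaling_sweep(samp, "density", c(5, 6, 7, 8), reps = 40), "4-fold")
  expect_error(scaling_sweep(samp, "density", c(5, 10, 20, 50), reps = 2), ">= 10")
})

test_that("tidiers expose per-hop records and one-row summaries", {
  mod <- unit_model(density_per_um2 = 25)
  res <- simulate_conduction(mod, 50, seed = 4)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("hop_index", "theta_rad", "r_um", "hop_time_ns"))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$total_time_ns, sum(td$hop_time_ns))

  f <- scaling_sweep(propagation_model(geometry_mode = "nominal"),
    "density", c(5, 10, 20, 50),
    reps = 10, length_um = 100
  )
  expect_identical(nrow(tidy(f)), 2L)
  expect_equal(glance(f)$slope, 0.5, tolerance = 1e-10)
})
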