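test_that("radiogenic heating follows the decay law", {
  one <- data.frame(isotope = "x", half_life_yr = 2e6,
                    power_W_per_kg_rock = 4e-8)
  expect_equal(radiogenic_heating(2e6, one), 2e-8)
  expect_equal(radiogenic_heating(0, one), 4e-8)
  # 26Al decline between the two reference formation times
  inv <- isotope_inventory()
  al <- inv[inv$isotope == "al26", ]
  ratio <- radiogenic_heating(3.5e6, al) / radiogenic_heating(0.5e6, al)
  expect_equal(ratio, 2^(-3.0 / 0.717), tolerance = 1e-10)
  expect_equal(radiogenic_heating(1e6, empty_inventory()), 0)
  expect_error(radiogenic_heating(-1, inv), "non-negative")
})

test_that("inventory contains the six canonical isotopes", {
  inv <- isotope_inventory()
  expect_setequal(inv$isotope, c("al26", "fe60", "k40", "th232", "u235", "u238"))
  expect_true(all(inv$half_life_yr > 0))
  expect_true(all(inv$power_W_per_kg_rock >= 0))
  # 26Al dominates at CAI
  expect_gt(inv$power_W_per_kg_rock[inv$isotope == "al26"],
            sum(inv$power_W_per_kg_rock[inv$isotope != "al26"]) * 100)
})

test_that("no heat source leaves the body isothermal", {
  cf <- quick_config(n = 40, t_end_yr = 1e6, inventory = empty_inventory())
  f <- simulate_thermal(cf)
  expect_equal(max(abs(f$temperature - 150)), 0, tolerance = 1e-9)
})

test_that("constant source relaxes to the analytic conduction steady state", {
  cf <- quick_config(radius_km = 2, n = 100, t_end_yr = 3e6, dt = 2e3,
                     inventory = constant_inventory(1e-8))
  f <- simulate_thermal(cf)
  k <- bulk_conductivity(cf)
  q <- (1 - cf$porosity) * cf$rho_rock * 1000 * 1e-8
  r_m <- f$radii_km * 1000
  R <- cf$radius_km * 1000
  T_ana <- cf$boundary_temperature + q * (R^2 - r_m^2) / (6 * k)
  T_num <- f$temperature[, ncol(f$temperature)]
  expect_lt(max(abs(T_num - T_ana) / (T_ana - cf$boundary_temperature)), 0.01)
})

test_that("discrete energy balance closes", {
  cf <- quick_config(radius_km = 2, n = 60, t_end_yr = 2e6,
                     inventory = constant_inventory(1e-8))
  f <- simulate_thermal(cf)
  eb <- energy_balance(f)
  expect_lt(eb$relative_residual, 0.01)   # backward Euler: ~round-off
  expect_gt(eb$input_J, 0)
})

test_that("center is a symmetry point and the surface stays pinned", {
  cf <- quick_config(radius_km = 2, n = 100, t_end_yr = 2e6,
                     inventory = constant_inventory(1e-8))
  f <- simulate_thermal(cf)
  n <- ncol(f$temperature)
  # zero-gradient center: innermost two cells nearly identical
  dT_center <- abs(f$temperature[1, n] - f$temperature[2, n])
  dT_body <- max(f$temperature[, n]) - min(f$temperature[, n])
  expect_lt(dT_center / dT_body, 5e-3)
  # Dirichlet surface: interpolated boundary value equals T_s
  expect_equal(temperature_at(f, cf$radius_km)[n],
               cf$boundary_temperature)
})

test_that("peak-temperature profile is non-increasing outward", {
  cf <- quick_config(radius_km = 3, n = 60, t_end_yr = 3e6)
  f <- simulate_thermal(cf)
  prof <- max_temperature_profile(f)
  expect_true(all(diff(prof$t_max_K) <= 1e-9))
  # constant-in-time field: profile equals that constant
  g <- thermal_field(1:5, c(0, 10), matrix(200, 5, 2))
  expect_equal(max_temperature_profile(g)$t_max_K, rep(200, 5))
})

test_that("later formation gives a cooler core; larger bodies melt deeper", {
  f_early <- simulate_thermal(quick_config(radius_km = 6, t_form_myr = 1,
                                           n = 60, t_end_yr = 4e6, dt = 1e4))
  f_late <- simulate_thermal(quick_config(radius_km = 6, t_form_myr = 2.5,
                                          n = 60, t_end_yr = 4e6, dt = 1e4))
  expect_gt(max(f_early$temperature[1, ]), max(f_late$temperature[1, ]))
  melted_frac <- function(R) {
    f <- simulate_thermal(quick_config(radius_km = R, t_form_myr = 1.5,
                                       n = 60, t_end_yr = 4e6, dt = 1e4))
    mean(max_temperature_profile(f)$t_max_K >= 273.15)
  }
  fr <- vapply(c(3, 10, 40), melted_frac, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("solution is grid-converged on refinement", {
  base <- quick_config(radius_km = 4, t_form_myr = 1, n = 60,
                       t_end_yr = 3e6, dt = 5e3)
  fine <- quick_config(radius_km = 4, t_form_myr = 1, n = 120,
                       t_end_yr = 3e6, dt = 5e3)
  fa <- simulate_thermal(base)
  fb <- simulate_thermal(fine)
  pa <- max_temperature_profile(fa)
  pb <- max_temperature_profile(fb)
  interp <- stats::approx(pb$radius_km, pb$t_max_K, pa$radius_km,
                          rule = 2)$y
  expect_lt(max(abs(pa$t_max_K - interp)), 1)
})

test_that("liquid-water window analytics handle toy fields", {
  # boxcar history through the thermal_field container
  box <- toy_thermal_history("boxcar", t_end = 3e6, t_on = 1e6, t_off = 2e6,
                             cold = 150, warm = 300, n = 3001)
  f <- thermal_field(c(1, 2), box$time_yr,
                     rbind(box$temperature_K, box$temperature_K))
  w <- liquid_window(f, 1.5)
  expect_true(w$ever)
  expect_equal(w$duration_yr, 1e6, tolerance = 1e-2)
  # never melting
  cold <- thermal_field(c(1, 2), c(0, 1e6), matrix(150, 2, 2))
  wc <- liquid_window(cold, 1)
  expect_false(wc$ever)
  expect_identical(wc$duration_yr, 0)
  expect_error(liquid_window(f, 99), "outside the grid")
  # ramp crossing matches the linear-interpolation oracle
  ramp <- toy_thermal_history("ramp", t_end = 1e6, T_start = 150,
                              T_stop = 350, n = 101)
  fr <- thermal_field(c(1, 2), ramp$time_yr,
                      rbind(ramp$temperature_K, ramp$temperature_K))
  t_cross <- 1e6 * (273.15 - 150) / (350 - 150)
  expect_equal(liquid_window(fr, 1)$onset_yr, t_cross, tolerance = 1e-9)
})
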