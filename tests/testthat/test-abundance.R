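test_that("catalyst yields scale pentose to ribose in the measured order", {
  expect_equal(apply_yield(2.5e-6, "Ca(OH)2"), 1.025e-7)
  expect_equal(apply_yield(0, "KOH"), 0)
  outs <- vapply(names(catalyst_yields()), function(cat)
    apply_yield(1e-5, cat), numeric(1))
  expect_equal(names(sort(outs, decreasing = TRUE)),
               c("Ca(OH)2", "CaCO3", "K2CO3", "KOH"))
  expect_error(apply_yield(1e-6, "NaOH"), "valid options")
  expect_true(all(catalyst_yields() > 0 & catalyst_yields() < 1))
})

test_that("bulk-mass conversion uses the rock+ice baseline", {
  f_ice <- ice_mass_fraction()
  expect_equal(f_ice, 0.1834 / 2.5834, tolerance = 1e-6)
  # lower-bound plateau: 1.025e-7 mol/mol(H2O) is about 61 ppb of bulk
  ppb <- molar_to_mass_ppb(1.025e-7)
  expect_equal(ppb, 1.025e-7 * (150.13 / 18.015) * f_ice * 1e9)
  expect_equal(ppb, 61, tolerance = 0.01)
  expect_identical(molar_to_mass_ppb(0), 0)
})

test_that("radial profile is flat inside the synthesized region", {
  # toy field: warm interior, cold skin
  radii <- seq(0.5, 9.5, by = 1)
  temps <- c(rep(320, 7), rep(200, 3))
  f <- thermal_field(radii, c(0, 1e6), cbind(temps, temps),
                     planetesimal_config(10, 1, n_radial_cells = 10))
  sc <- table1_scenario("lower")
  rp <- radial_profile(f, sc)
  expect_s3_class(rp, "abundance_profile")
  oracle <- limiting_reagent_conversion(6.6e-4, 5e-6)$pentose
  inside <- rp$t_max_K >= 273.15
  expect_equal(rp$pentose_molar[inside], rep(oracle, sum(inside)),
               tolerance = 1e-6)
  expect_true(all(rp$pentose_molar[!inside] == 0))
  # nonzero exactly where the melting point was reached
  expect_identical(rp$ribose_ppb > 0, inside)
})

test_that("upper/lower scenario ratio is the stoichiometric factor 80", {
  radii <- c(1, 2)
  f <- thermal_field(radii, c(0, 1e6), matrix(300, 2, 2),
                     planetesimal_config(2.5, 1, n_radial_cells = 3))
  lo <- radial_profile(f, table1_scenario("lower"))
  hi <- radial_profile(f, table1_scenario("upper"))
  expect_equal(hi$ribose_ppb / lo$ribose_ppb, rep(80, 2), tolerance = 1e-6)
})

test_that("pipeline is linear in the limiting reactant and catalyst-neutral", {
  f <- thermal_field(c(1, 2), c(0, 1e6), matrix(300, 2, 2),
                     planetesimal_config(2.5, 1, n_radial_cells = 3))
  base_sc <- composition_scenario(6.6e-4, 2e-5)
  doub_sc <- composition_scenario(6.6e-4, 4e-5)
  base <- radial_profile(f, base_sc)
  doub <- radial_profile(f, doub_sc)
  expect_equal(doub$ribose_ppb, 2 * base$ribose_ppb, tolerance = 1e-6)
  # catalyst affects ribose only, not the pentose pool
  koh <- radial_profile(f, composition_scenario(6.6e-4, 2e-5, catalyst = "KOH"))
  expect_equal(koh$pentose_molar, base$pentose_molar)
  expect_equal(koh$ribose_molar / koh$pentose_molar,
               rep(catalyst_yields()[["KOH"]], 2))
})

test_that("end-to-end plateau equals the closed-form oracle for sampled scenarios", {
  f <- thermal_field(c(1, 2), c(0, 1e6), matrix(300, 2, 2),
                     planetesimal_config(2.5, 1, n_radial_cells = 3))
  for (sc in sample_scenarios(10, seed = 5)) {
    rp <- radial_profile(f, sc)
    oracle <- limiting_reagent_conversion(
      sc$concentrations[["formaldehyde"]],
      sc$concentrations[["glycolaldehyde"]])$pentose
    expected <- molar_to_mass_ppb(apply_yield(oracle, sc$catalyst))
    expect_equal(compare_to_meteorites(rp)$plateau_ppb, expected,
                 tolerance = 0.01)
  }
})

test_that("temporal profile onsets with the liquid-water window", {
  box <- toy_thermal_history("boxcar", t_end = 3e6, t_on = 1e6, t_off = 2e6,
                             cold = 150, warm = 300, n = 301)
  f <- thermal_field(c(1, 2), box$time_yr,
                     rbind(box$temperature_K, box$temperature_K),
                     planetesimal_config(2.5, 1, n_radial_cells = 3))
  tp <- temporal_profile(f, 1.5, table1_scenario("lower"))
  expect_equal(onset_time(tp), 1e6, tolerance = 1e-2)
  expect_true(all(diff(tp$ribose_ppb) >= 0))
  # cold shell never synthesizes
  cold <- thermal_field(c(1, 2), c(0, 1e6), matrix(150, 2, 2))
  tpc <- temporal_profile(cold, 1, table1_scenario("lower"))
  expect_true(all(tpc$ribose_ppb == 0))
  expect_true(is.na(onset_time(tpc)))
})

test_that("meteorite comparison reports the deviation factor", {
  mk <- function(ppb) {
    df <- data.frame(time_yr = 1:2, temperature_K = 300,
                     pentose_molar = 1, ribose_molar = 1, ribose_ppb = ppb)
    structure(df, class = c("abundance_profile", "data.frame"),
              axis = "time", catalyst = "KOH", scenario = "custom")
  }
  expect_equal(compare_to_meteorites(mk(10))$factor, 1)
  expect_equal(compare_to_meteorites(mk(50))$factor, 2)
  expect_equal(compare_to_meteorites(mk(2.25))$factor, 2)
  expect_error(compare_to_meteorites(mk(0)), "no synthesis")
})
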