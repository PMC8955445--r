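test_that("element totals follow the molecular formulas", {
  expect_equal(element_totals(c(water = 1)), c(C = 0, H = 2, O = 1))
  # Eq-1 stoichiometry balances: 1 CH2O + 2 C2H4O2 has ribose's composition
  lhs <- element_totals(c(formaldehyde = 1, glycolaldehyde = 2))
  rhs <- element_totals(c(ribose = 1))
  expect_equal(lhs, rhs)
  expect_equal(unname(lhs), c(5, 10, 5))
  # lower-bound scenario, hand-summed
  st <- mixture_state(6.6e-4, 5e-6)
  tot <- element_totals(st)
  expect_equal(tot[["C"]], 6.6e-4 + 2 * 5e-6)
  expect_equal(tot[["H"]], 2 + 2 * 6.6e-4 + 4 * 5e-6)
  expect_equal(tot[["O"]], 1 + 6.6e-4 + 2 * 5e-6)
  expect_error(element_totals(c(glucose = 1)), "unknown species")
})

test_that("limiting-reagent closed form implements the pathway stoichiometry", {
  lo <- limiting_reagent_conversion(6.6e-4, 5e-6)
  expect_equal(lo$pentose, 2.5e-6)
  expect_equal(lo$limiting, "glycolaldehyde")
  expect_equal(lo$leftover_gly, 0)
  hi <- limiting_reagent_conversion(6.6e-4, 4e-4)
  expect_equal(hi$pentose, 2e-4)
  expect_equal(hi$limiting, "glycolaldehyde")
  expect_equal(limiting_reagent_conversion(0, 0.123)$pentose, 0)
  expect_equal(limiting_reagent_conversion(1e-5, 1)$limiting, "formaldehyde")
  expect_error(limiting_reagent_conversion(-1, 1), "non-negative")
})

test_that("minimizer matches the limiting-reagent oracle when favoured", {
  tab <- gibbs_table()
  for (gly in c(5e-6, 4.7e-5, 4e-4)) {
    st <- mixture_state(6.6e-4, gly, temperature = 298.15)
    eq <- minimize_gibbs(st, tab)
    oracle <- limiting_reagent_conversion(6.6e-4, gly)$pentose
    expect_lt(abs(eq$amounts[["ribose"]] - oracle) / oracle, 0.01)
    # reactants effectively exhausted
    expect_lt(eq$amounts[["glycolaldehyde"]], 1e-9 * gly)
  }
})

test_that("water-only and unfavourable systems do not react", {
  tab <- gibbs_table()
  st <- minimize_gibbs(mixture_state(0, 0), tab)
  expect_identical(unname(st$amounts),
                   unname(c(water = 1, formaldehyde = 0,
                            glycolaldehyde = 0, ribose = 0)))
  # sign-flipped energies make the reaction unfavourable
  flip <- tab
  flip$energies <- -flip$energies
  eq <- minimize_gibbs(mixture_state(6.6e-4, 5e-6, temperature = 300), flip)
  expect_lt(eq$amounts[["ribose"]], 1e-12 * 2.5e-6)
})

test_that("equilibration conserves C, H and O for random states", {
  tab <- gibbs_table()
  set.seed(42)
  for (i in 1:200) {
    st <- mixture_state(stats::runif(1, 0, 1e-3), stats::runif(1, 0, 1e-3),
                        temperature = stats::runif(1, 273.15, 500))
    eq <- minimize_gibbs(st, tab)
    expect_true(all(eq$amounts >= 0))
    rel <- abs(element_totals(eq) - element_totals(st)) /
      pmax(element_totals(st), 1e-30)
    expect_lt(max(rel), 1e-10)
  }
})

test_that("pentose output is invariant under glycolaldehyde energy shifts", {
  tab <- gibbs_table()
  st <- mixture_state(6.6e-4, 5e-6, temperature = 330)
  base <- minimize_gibbs(st, tab)$amounts[["ribose"]]
  for (off in c(-20e3, 20e3)) {
    expect_lt(abs(reaction_delta_g(tab, 330, gly_offset = off)), 3e5)
    expect_lt(sign(reaction_delta_g(tab, 330, gly_offset = off)), 0)
    pert <- minimize_gibbs(st, tab, gly_offset = off)$amounts[["ribose"]]
    expect_lt(abs(pert - base) / base, 0.01)
  }
})

test_that("time iteration freezes below the melting point and is monotone", {
  tab <- gibbs_table()
  sc <- table1_scenario("lower")
  # never warm enough: identically zero
  cold <- toy_thermal_history("constant", t_end = 1e6, level = 150)
  traj <- time_iterated_equilibrium(cold$time_yr, cold$temperature_K, sc, tab)
  expect_true(all(traj$pentose_molar == 0))
  # cold -> warm -> cold boxcar: single jump to the limiting-reagent value
  box <- toy_thermal_history("boxcar", t_end = 3e6, t_on = 1e6, t_off = 2e6,
                             cold = 150, warm = 300, n = 301)
  traj <- time_iterated_equilibrium(box$time_yr, box$temperature_K, sc, tab)
  oracle <- limiting_reagent_conversion(6.6e-4, 5e-6)$pentose
  expect_equal(max(traj$pentose_molar), oracle, tolerance = 1e-6)
  expect_true(all(diff(traj$pentose_molar) >= 0))
  warm_idx <- which(box$temperature_K >= 273.15)
  expect_equal(traj$pentose_molar[warm_idx[1]], oracle, tolerance = 1e-6)
  expect_equal(traj$pentose_molar[warm_idx[1] - 1], 0)
  # value persists after re-freezing
  expect_equal(traj$pentose_molar[nrow(traj)], max(traj$pentose_molar))
})
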