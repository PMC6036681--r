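# Kinetic simulator: rate stoichiometry, integration, observation layer.

test_that("biological rates vanish without biomass and obey WGS stoichiometry", {
  p <- kinetic_params(mu_max = 0.5, q_o2 = 0.1, q_wgs = 0.1, q_aco = 0.05,
                      q_fhl = 0.05, k_d = 0.01, formate_pool = 0.2)
  d0 <- wgs_rates(c(X = 0, o2 = 0.5, co = 3, Fp = 0.2), p)
  expect_true(all(abs(d0[c("X", "h2", "o2", "co", "co2")]) == 0))

  # anoxic, WGS only: dH2 = dCO2 = -dCO
  p <- kinetic_params(q_wgs = 0.1)
  d <- wgs_rates(c(X = 1, o2 = 0, co = 3), p)
  expect_gt(d[["h2"]], 0)
  expect_equal(d[["h2"]], -d[["co"]])
  expect_equal(d[["co2"]], -d[["co"]])
  expect_equal(d[["n2"]], 0)

  # at p_O2 = K_I_O2 the WGS rate is half its anoxic value
  b <- bottle_spec()
  p <- kinetic_params(q_wgs = 0.1, K_I_O2 = 1e-3)
  n_at <- 1e-3 * 200 / (0.0831446 * b$incubation_temperature)  # p_O2 = K_I
  d_anox <- wgs_rates(c(X = 1, o2 = 0, co = 3), p)
  d_half <- wgs_rates(c(X = 1, o2 = n_at, co = 3), p)
  expect_equal(d_half[["h2"]], d_anox[["h2"]] / 2, tolerance = 1e-12)

  expect_error(wgs_rates(c(X = -1, co = 3), p), "negative state")
})

test_that("identical seeds give identical observations and zero noise is reproducible", {
  pre1 <- scenario_preset("dsm2542", noise = "default", seed = 7)
  pre2 <- scenario_preset("dsm2542", noise = "default", seed = 7)
  s1 <- simulate_wgs(pre1)$series$points
  s2 <- simulate_wgs(pre2)$series$points
  expect_identical(s1, s2)

  pre3 <- scenario_preset("dsm2542", noise = "default", seed = 8)
  expect_false(identical(s1, simulate_wgs(pre3)$series$points))

  n1 <- simulate_wgs(scenario_preset("dsm2542", seed = 1))$series$points
  n2 <- simulate_wgs(scenario_preset("dsm2542", seed = 99))$series$points
  expect_identical(n1, n2)  # no noise: seed cannot matter
})

test_that("a dead bottle shows constant composition and pressure drops only at samplings", {
  sim <- simulate_wgs(scenario_preset("abiotic_control"))
  p <- sim$series$points
  x <- as.matrix(p[paste0("x_", GAS_SPECIES)])
  expect_true(all(abs(sweep(x, 2, x[1, ], "-")) < 1e-12))
  expect_true(all(diff(p$p_before_bar) < 0))
  expect_true(all(p$p_after_bar < p$p_before_bar))
})

test_that("carbon bookkeeping couples CO consumed to CO-derived CO2 exactly", {
  for (name in c("dsm2542", "toebii", "thermodenitrificans")) {
    sim <- simulate_wgs(scenario_preset(name))
    gt <- ground_truth_balance(sim)
    pw <- gt$pathways
    co_reacted <- pw[["c_wgs"]] + pw[["c_aco"]] + pw[["c_loss"]]
    co_derived_co2 <- gt$q[["co2"]] - sim$params$y_co2_per_o2 * pw[["c_resp"]] -
      pw[["c_fhl"]]
    expect_equal(co_derived_co2, co_reacted, tolerance = 1e-10)
    expect_equal(unname(-gt$q["co"]), co_reacted, tolerance = 1e-12)
  }
})

test_that("trajectories are monotone where the biology is one-directional", {
  sim <- simulate_wgs(scenario_preset("dsm2542"))
  # cumulative net production is monotone: withdrawals are credited back
  tab <- as.data.frame(gas_balance(sim$series))
  expect_true(all(diff(tab$q_h2) >= -1e-9))
  expect_true(all(diff(tab$q_co2) >= -1e-9))
  expect_true(all(diff(tab$q_co) <= 1e-9))
  expect_true(all(diff(tab$q_o2) <= 1e-9))
  # raw headspace amounts are monotone too (reaction and withdrawal pull the
  # same way for O2 and CO)
  tr <- sim$truth$trajectory
  expect_true(all(diff(tr$o2) <= 1e-12))
  expect_true(all(diff(tr$co) <= 1e-9))
  expect_true(min(as.matrix(tr[c("h2", "o2", "n2", "co", "co2", "X", "Fp")]))
              >= -1e-9)
  # biomass has a single interior maximum when k_d > 0
  x <- tr$X
  peak <- which.max(x)
  expect_gt(peak, 1)
  expect_lt(peak, length(x))
  expect_true(all(diff(x[peak:length(x)]) <= 1e-12))
})

test_that("withdrawal ledger matches the observed pressure-drop ledger", {
  sim <- simulate_wgs(scenario_preset("dsm2542"))
  bal <- gas_balance(sim$series)
  tab <- as.data.frame(bal)
  got <- as.matrix(tab[paste0("rem_", GAS_SPECIES)])
  expect_equal(unname(got), unname(sim$truth$ledger), tolerance = 1e-9)
})

test_that("the accounting pipeline recovers the simulator's ground truth", {
  for (name in c("dsm2542", "toebii", "thermodenitrificans")) {
    sim <- simulate_wgs(scenario_preset(name))
    gt <- ground_truth_balance(sim)
    q <- summary(gas_balance(sim$series))$final_net_production
    active <- abs(gt$q) > 0.01
    expect_true(all(abs(q[active] - gt$q[active]) / abs(gt$q[active]) < 0.01),
                label = paste("recovery within 1% for", name))
  }
})

test_that("scenario presets reflect the strain biology", {
  toe <- scenario_preset("toebii")
  expect_gt(toe$params$q_aco, 0)
  expect_equal(toe$params$q_wgs, 0)
  expect_equal(toe$params$q_fhl, 0)
  expect_equal(unname(toe$scenario$initial_amounts["o2"]), 0.66)

  th <- scenario_preset("thermodenitrificans")
  expect_gt(th$params$k_co_loss, 0)
  expect_equal(th$params$q_wgs + th$params$q_aco + th$params$q_fhl, 0)

  expect_error(scenario_preset("unknown_strain"), "arg")

  # total fill is 1 bar / 298.15 K over 200 ml
  dsm <- scenario_preset("dsm2542")
  expect_equal(sum(dsm$scenario$initial_amounts),
               200 / (0.0831446 * 298.15), tolerance = 1e-9)
})

test_that("invalid scenarios are rejected", {
  expect_error(wgs_scenario(sampling_times = c(0, 4, 4), initial_amounts = c(n2 = 5)),
               "strictly increasing")
  expect_error(wgs_scenario(sampling_times = c(0, 0.005, 1), initial_amounts = c(n2 = 5)),
               "integration_step")
  expect_error(kinetic_params(mu_max = -1), "non-negative")
  b <- bottle_spec(total_volume = 10, initial_liquid_volume = 5)
  sc <- wgs_scenario(bottle = b, initial_amounts = c(n2 = 0.2),
                     sampling_times = c(0, 1), gas_sample_volume = 6)
  expect_error(simulate_wgs(sc), "oversampled")
})
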