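# Permeation solver: closed-form membrane limits, independent spectral
# oracle, conservation, convergence and monotonicity.

test_that("zero dose yields identically zero flux and accumulation", {
  dom <- skin_domain(toy_coeffs(), toy_params(), model_config())
  sim <- simulate_permeation(dom,
                             exposure_scenario(0, 10,
                                               solubility_vehicle_ug_cm3 = 1),
                             model_config())
  expect_true(all(sim$flux == 0))
  expect_true(all(sim$accumulation == 0))
  expect_equal(terminal_flux(sim), 0)
})

test_that("SC-limited saturated donor matches the membrane closed form", {
  # make ED/DE transparent so the SC behaves as a single membrane
  co <- toy_coeffs(d = c(5e-7, 10, 10), k = c(5, 1, 1))
  cfg <- model_config(nodes = c(sc = 60L, ed = 8L, de = 8L))
  par <- toy_params(h_sc = 43, h_ed = 5, h_de = 5)
  dom <- skin_domain(co, par, cfg)
  Cv <- 500
  scen <- exposure_scenario(1e9, 300, solubility_vehicle_ug_cm3 = Cv,
                            donor_regime = "saturated")
  sim <- simulate_permeation(dom, scen, cfg, times = seq(0, 300, by = 0.5))

  h <- 43e-4
  J_ss <- co$k_sc_w * co$d_sc * Cv / h
  lag <- h^2 / (6 * co$d_sc)
  expect_gt(300, 5 * lag)  # past five lag times
  expect_equal(terminal_flux(sim), J_ss, tolerance = 0.02)
  expect_equal(flux_slope(sim), J_ss, tolerance = 0.02)

  # lag time from extrapolating the late linear Q(t)
  late <- sim$time > 200
  fit <- stats::lm(sim$accumulation[late] ~ sim$time[late])
  lag_sim <- -unname(stats::coef(fit)[1] / stats::coef(fit)[2])
  expect_equal(lag_sim, lag, tolerance = 0.02)
})

test_that("solver agrees with an independent spectral reference", {
  co <- toy_coeffs()
  par <- toy_params()
  cfg <- model_config(nodes = c(sc = 40L, ed = 40L, de = 40L))
  dom <- skin_domain(co, par, cfg)
  Cv <- 100
  T_h <- 8
  scen <- exposure_scenario(1e9, T_h, solubility_vehicle_ug_cm3 = Cv,
                            donor_regime = "saturated")
  sim <- simulate_permeation(dom, scen, cfg)
  ref <- spectral_reference(c(30, 50, 100),
                            c(co$d_sc, co$d_ed, co$d_de),
                            c(co$k_sc_w, co$k_ed_w, co$k_de_w),
                            Cv, T_h, cells_per_layer = 80)
  expect_equal(sim$accumulation[length(sim$accumulation)], ref$Q,
               tolerance = 0.01)
  expect_equal(terminal_flux(sim), ref$J, tolerance = 0.01)
})

test_that("mass is conserved and flux is non-negative", {
  co <- toy_coeffs()
  cfg <- model_config()
  dom <- skin_domain(co, toy_params(), cfg)

  scen <- exposure_scenario(50, 24, solubility_vehicle_ug_cm3 = 1000,
                            vehicle_thickness_um = 1000)
  sim <- simulate_permeation(dom, scen, cfg, times = seq(0, 24, by = 0.05))
  expect_equal(sim$donor_regime, "finite")
  expect_lt(sim$mass_balance_error, 1e-3)
  expect_true(all(sim$flux >= 0))
  # yQ non-decreasing and consistent with the trapezoid integral of yJ
  expect_true(all(diff(sim$accumulation) >= -1e-12))
  trap <- sum(diff(sim$time) *
                (head(sim$flux, -1) + tail(sim$flux, -1)) / 2)
  expect_equal(trap, sim$accumulation[length(sim$accumulation)],
               tolerance = 0.01)

  # saturated regime: cumulative influx balances skin uptake + receptor
  scen_s <- exposure_scenario(1e6, 24, solubility_vehicle_ug_cm3 = 200,
                              donor_regime = "saturated")
  sim_s <- simulate_permeation(dom, scen_s, cfg)
  expect_lt(sim_s$mass_balance_error, 1e-3)

  # finite donor, long time: everything ends in the receptor (perfect sink)
  scen_l <- exposure_scenario(10, 2000, solubility_vehicle_ug_cm3 = 1000,
                              vehicle_thickness_um = 500)
  sim_l <- simulate_permeation(dom, scen_l, cfg, times = c(0, 2000))
  expect_equal(sim_l$accumulation[2], 10, tolerance = 5e-3)
})

test_that("grid refinement changes the terminal flux by under 1%", {
  co <- toy_coeffs()
  scen <- exposure_scenario(50, 24, solubility_vehicle_ug_cm3 = 1000)
  cfg1 <- model_config()
  cfg2 <- model_config(nodes = c(sc = 30L, ed = 30L, de = 60L))
  s1 <- simulate_permeation(skin_domain(co, toy_params(), cfg1), scen, cfg1,
                            times = c(0, 24))
  s2 <- simulate_permeation(skin_domain(co, toy_params(), cfg2), scen, cfg2,
                            times = c(0, 24))
  expect_equal(terminal_flux(s1), terminal_flux(s2), tolerance = 0.01)
})

test_that("thinner stratum corneum strictly increases terminal flux", {
  co <- toy_coeffs(d = c(5e-7, 1e-3, 1e-3), k = c(5, 0.8, 0.8))
  cfg <- model_config()
  scen <- exposure_scenario(1e6, 72, solubility_vehicle_ug_cm3 = 300,
                            donor_regime = "saturated")
  fluxes <- vapply(c(43, 35, 28, 20), function(h) {
    dom <- skin_domain(co, toy_params(h_sc = h), cfg)
    terminal_flux(simulate_permeation(dom, scen, cfg, times = c(0, 72)))
  }, numeric(1))
  expect_true(all(diff(fluxes) > 0))
})

test_that("donor regime resolution follows the dose/solubility rule", {
  s1 <- exposure_scenario(100, 10, solubility_vehicle_ug_cm3 = 600,
                          vehicle_thickness_um = 10000)
  expect_equal(pedperm:::resolve_donor_regime(s1), "finite")   # 600 capacity
  s2 <- exposure_scenario(1000, 10, solubility_vehicle_ug_cm3 = 600,
                          vehicle_thickness_um = 10000)
  expect_equal(pedperm:::resolve_donor_regime(s2), "saturated")
  expect_error(exposure_scenario(10, 5, donor_regime = "saturated"),
               "solubility")
  expect_error(exposure_scenario(10, -5), "positive")
})
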