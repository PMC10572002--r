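test_that("core-to-skin conduction with distributed generation", {
  expect_equal(core_to_skin(0, 0.3, 0.5, 39), 39)
  # hand evaluation of q_v R^2 / (4k)
  expect_equal(39 - core_to_skin(1000, 0.3, 0.5, 39), 1000 * 0.09 / (4 * 0.5))
  # doubling conductivity halves the gradient
  d1 <- 39 - core_to_skin(500, 0.2, 0.5, 39)
  d2 <- 39 - core_to_skin(500, 0.2, 1.0, 39)
  expect_equal(d1, 2 * d2)
  # spheroid divisor 6
  expect_equal(39 - core_to_skin(600, 0.1, 0.5, 39, "spheroid"),
               600 * 0.01 / (6 * 0.5))
})

test_that("respiratory evaporation: ventilation tied to oxygen demand", {
  # saturated ambient at exhale temperature: no gradient, no flux
  r0 <- respiratory_evaporation(1000, 35, 100, panting = 1, tcore = 39)
  expect_equal(r0$g_per_h, 0)
  # doubling metabolic rate doubles the flux at fixed air state
  r1 <- respiratory_evaporation(750, 20, 50)
  r2 <- respiratory_evaporation(1500, 20, 50)
  expect_equal(r2$g_per_h, 2 * r1$g_per_h)
  # hand evaluation at 1500 W, 20 C, 50% RH: vent = MR/(20.1e6 J/m3 O2)
  # / (0.2095 * 0.15); exhale saturated at 35 C
  vent <- 1500 / (20.1 * 1e6) / (0.2095 * 0.15)
  dp <- bovitherm:::sat_vapour_density(35) -
    0.5 * bovitherm:::sat_vapour_density(20)
  expect_equal(r2$g_per_h, vent * dp * 3600, tolerance = 1e-9)
  expect_gt(r2$g_per_h, 0)
  expect_error(respiratory_evaporation(1000, 20, 50, panting = 9), "panting")
})

test_that("cutaneous evaporation honours the physiological cap", {
  # full recruitment, huge gradient, high wind: flux clamps at the cap
  hot <- cutaneous_evaporation(1, 5, tskin_c = 40, ta_c = 45, rh_pct = 5,
                               wind_ms = 8, h_Wm2K = 500)
  expect_equal(hot$flux_g_m2h, 400)
  # no vapour-pressure gradient: nothing evaporates
  none <- cutaneous_evaporation(1, 5, tskin_c = 25, ta_c = 25, rh_pct = 100)
  expect_equal(none$g_per_h, 0)
  # linear in area at fixed per-area flux
  a1 <- cutaneous_evaporation(0.5, 1, 38, 25, 40)
  a3 <- cutaneous_evaporation(0.5, 3, 38, 25, 40)
  expect_equal(a3$g_per_h, 3 * a1$g_per_h)
  expect_error(cutaneous_evaporation(1.4, 1, 38, 25, 40), "sweat_level")
})

test_that("coat-surface node matches a brute-force 1 mK scan", {
  coat <- coat_spec(depth_cm = 0.336)
  env <- chamber_env(22, 1.5, 60, solar_Wm2 = 0)
  d <- 0.6; len <- 1.6; area <- pi * d * len
  tskin <- 38.2
  q_sol <- 120                      # absorbed solar per m2 at the surface
  pb <- part_balance(d, len, area, "cylinder", tskin, env, coat,
                     q_sol_Wm2 = q_sol)
  # brute force: scan the coat-surface temperature on a 1 mK grid and pick
  # the interface balance root
  p <- bt_params()
  hc <- convection_coefficient(d, env$wind_ms, env$tair_c,
                               (39 + env$tair_c) / 2)   # solver's guess convention
  rad_frac <- p$rad_area_frac * p$coat_emis
  tf_grid <- seq(env$tair_c - 2, tskin + 2, by = 0.001)
  resid <- vapply(tf_grid, function(tf) {
    rf <- fur_resistance(coat, (tskin + tf) / 2 + 273.15, d / 2)
    cond <- (tskin - tf) / rf
    out <- hc * (tf - env$tair_c) +
      rad_frac * p$sigma * ((tf + 273.15) ^ 4 - (env$tair_c + 273.15) ^ 4)
    cond - out + q_sol
  }, numeric(1))
  tf_best <- tf_grid[which.min(abs(resid))]
  rf_best <- fur_resistance(coat, (tskin + tf_best) / 2 + 273.15, d / 2)
  flux_best <- (tskin - tf_best) / rf_best * area
  expect_equal(pb$tfur_c, tf_best, tolerance = 0.002)
  expect_equal(pb$net_flux_W, flux_best, tolerance = 0.005 * abs(flux_best))
})

test_that("solar load strictly reduces net heat loss from a part", {
  coat <- coat_spec(depth_cm = 0.336)
  env <- chamber_env(20, 1, 50)
  base <- part_balance(0.6, 1.6, 3, "cylinder", 38, env, coat, q_sol_Wm2 = 0)
  sun <- part_balance(0.6, 1.6, 3, "cylinder", 38, env, coat, q_sol_Wm2 = 500)
  expect_lt(sun$net_flux_W, base$net_flux_W)
  # isothermal limit: everything at one temperature, no solar -> ~0 flux
  iso <- part_balance(0.6, 1.6, 3, "cylinder", 20, chamber_env(20, 1, 50),
                      coat)
  expect_lt(abs(iso$net_flux_W), 1e-6)
})

test_that("required generation closes the whole-animal balance", {
  env <- chamber_env(10, 1, 50)
  b <- solve_required_generation(nonlactating_643, env)
  expect_lt(abs(b$residual_W), 1e-3)
  # closure identity of the itemised budget
  expect_lt(abs(b$q_gen_W + b$q_sol_W + b$q_ir_in_W -
                  (b$q_conv_W + b$q_cond_W + b$q_evap_cut_W +
                     b$q_evap_resp_W + b$q_ir_out_W)), 5e-3)
  # colder air requires strictly more generation (sub-thermoneutral)
  q <- vapply(c(15, 10, 5, 0, -5), function(t)
    solve_required_generation(nonlactating_643,
                              chamber_env(t, 1, 50))$q_gen_W, numeric(1))
  expect_true(all(diff(q) > 0))
})

test_that("single bare cylinder matches the closed-form balance", {
  geom <- single_cylinder_geometry()
  an <- animal_spec(mass_kg = 500, coat = bare_coat)
  st <- regulation_state(k_flesh = 0.8)
  env <- chamber_env(5, 2, 50)
  b <- solve_required_generation(an, env, st, params = no_resp_params,
                                 geom = geom)
  # independent closed form: Q = hc A (Ts - Ta) + eps sigma A (Ts^4 - Ta^4)
  # with Ts = Tcore - (Q/V) R^2/(4k)
  p <- no_resp_params
  d <- geom$parts$diameter_m; area <- geom$parts$area_m2
  hc <- convection_coefficient(d, env$wind_ms, env$tair_c,
                               (39 + env$tair_c) / 2, params = p)
  rad_frac <- p$rad_area_frac * p$coat_emis
  f <- function(q) {
    ts <- 39 - (q / geom$total_volume_m3) * (d / 2) ^ 2 / (4 * st$k_flesh)
    q - (hc * area * (ts - env$tair_c) +
           rad_frac * p$sigma * area *
             ((ts + 273.15) ^ 4 - (env$tair_c + 273.15) ^ 4))
  }
  q_ref <- uniroot(f, c(0, 5000), tol = 1e-9)$root
  expect_equal(b$q_gen_W, q_ref, tolerance = 1e-3)
})
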