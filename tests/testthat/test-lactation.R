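test_that("Wood lactation curve normalisation and support", {
  expect_equal(wood_yield(0, 36.4), 0)
  expect_equal(wood_yield(306, 36.4), 0)
  p <- bt_params()
  t_peak <- p$wood_b / p$wood_c
  expect_equal(wood_yield(t_peak, 36.4), 36.4, tolerance = 1e-6)
  # the peak really is the maximum
  tt <- seq(1, 305, by = 0.5)
  expect_equal(tt[which.max(wood_yield(tt, 36.4))], t_peak, tolerance = 0.5)
  expect_error(wood_yield(10, 30, b = -1), "b")
  expect_error(wood_yield(10, 30, c = 0), "c")
})

test_that("energy-corrected milk formula", {
  expect_equal(ecm(0, 0, 0), 0)
  # the barn herd average: 52.4 kg at 3.12% fat, 2.71% protein
  fat <- 52.4 * 0.0312; prot <- 52.4 * 0.0271
  expect_equal(fat, 1.63488)
  expect_equal(ecm(52.4, fat, prot), 48.03, tolerance = 1e-4)
  expect_equal(ecm(20, 0.6, 0.7), 2 * ecm(10, 0.3, 0.35))
  expect_error(ecm(-1, 0, 0), "non-negative")
})

test_that("milk energy flow from composition", {
  expect_equal(milk_energy(0, 3.2, 3.5), 0)
  # hand evaluation: kJ/kg = 10*(38.7*fat% + 23.9*prot% + 16.5*4.8)
  e <- milk_energy(36.4, 3.2, 3.5)
  expect_equal(e, 36.4 * 10 * (38.7 * 3.2 + 23.9 * 3.5 + 16.5 * 4.8) *
                 1000 / 86400, tolerance = 1e-9)
  expect_gt(milk_energy(30, 4.5, 3.5), milk_energy(30, 3.0, 3.5))
})

test_that("feed requirement scales with energy need and diet density", {
  f0 <- feed_requirement(500, 0, 0.65, c(HPF = 100))
  expect_gt(f0$dmi_kgd, 0)
  # doubling both energy terms doubles intake
  f2 <- feed_requirement(1000, 0, 0.65, c(HPF = 100))
  expect_equal(f2$dmi_kgd, 2 * f0$dmi_kgd)
  # the two forage dry-matter fractions drive as-fed mass
  fe <- feed_requirement(500, 800, 0.65, c(HEF = 100))
  fp <- feed_requirement(500, 800, 0.65, c(HPF = 100))
  expect_equal(fe$as_fed_kgd * 0.315, fe$dmi_kgd, tolerance = 1e-9)
  expect_equal(fp$as_fed_kgd * 0.775, fp$dmi_kgd, tolerance = 1e-9)
  expect_gt(fe$feed_water_kgd, fp$feed_water_kgd)
  expect_error(feed_requirement(500, 0, 1.2, c(HPF = 100)), "efficiency")
})

test_that("water balance itemisation and closure", {
  wb <- water_balance(15, c(HPF = 100), 30, 0.80, evap_kgd = 8)
  # fecal water from the fecal dry matter at 80% water content
  expect_equal(wb$fecal_water_kgd, wb$fecal_dm_kgd * 0.8 / 0.2)
  # 5 kg/d fecal DM at 80% -> 20 kg/d fecal water
  wb5 <- water_balance(5 / (1 - 0.62), c(HPF = 100), 0, 0.80, 0)
  expect_equal(wb5$fecal_water_kgd, 20, tolerance = 1e-9)
  # closure when the drinking floor is not binding
  expect_lt(abs(wb$residual_kgd), 1e-6)
  # high-energy forage carries far more feed water: less drinking needed
  we <- water_balance(15, c(HEF = 100), 30, 0.80, 8)
  wp <- water_balance(15, c(HPF = 100), 30, 0.80, 8)
  expect_lt(we$drinking_kgd, wp$drinking_kgd)
  expect_error(water_balance(15, c(HPF = 100), 30, 1, 8), "fecal")
})

test_that("feed efficiency of the 533 kg fixture is plausible", {
  an <- fixture_animal("literature")
  rest <- bt_params()$rest_coef * an$mass_kg ^ 0.75
  me <- milk_energy(an$milk_target_kgd, an$milk_fat_pct, an$milk_protein_pct)
  f <- feed_requirement(rest, me, an$milk_efficiency, an$diet_summer)
  e <- ecm(an$milk_target_kgd,
           an$milk_target_kgd * an$milk_fat_pct / 100,
           an$milk_target_kgd * an$milk_protein_pct / 100)
  eff <- e / f$dmi_kgd
  expect_gte(eff, 1.19)
  expect_lte(eff, 2.01)
})

test_that("monthly midpoint sampling reproduces the 305-day Wood integral", {
  cal <- bovitherm:::lactation_calendar(9, 5)
  expect_equal(sum(cal$n_lact), 305)
  approx <- sum(cal$n_lact * 36.4 * cal$mean_rel_yield)
  exact <- integrate(function(t) wood_yield(t, 36.4), 0, 305,
                     rel.tol = 1e-8)$value
  expect_equal(approx, exact, tolerance = 5e-3)
})
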