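test_that("solar position matches closed-form geometry", {
  # equator, equinox, solar noon: sun overhead
  eq <- solar_position(0, 0, 0, day_of_year = 80, solar_hour = 12)
  expect_lt(eq$zenith, 1)
  # zenith = |lat - declination| at noon
  z30 <- solar_position(30, 0, 0, 80, 12)
  expect_equal(z30$zenith, 30, tolerance = 1 / 30)
  # midnight at 60 N: sun below horizon
  expect_gt(solar_position(60, 0, 0, 80, 0)$zenith, 90)
  expect_error(solar_position(100, 0, 0, 80, 12), "latitude")
  expect_error(solar_position(45, 0, 0, 400, 12), "day_of_year")
})

test_that("solar flux follows the bulk-transmittance model", {
  # overhead sun, clear, sea level: S0 * tau^1
  f <- solar_flux(0, 0, 0)
  expect_equal(f$direct_normal, 1367 * 0.7, tolerance = 1e-3)
  # below horizon: both components zero
  f95 <- solar_flux(95, 0, 0.5)
  expect_identical(unname(f95$direct_normal), 0)
  expect_identical(unname(f95$diffuse_horizontal), 0)
  # full overcast: beam extinguished, diffuse survives
  fc <- solar_flux(30, 0, 1)
  expect_equal(fc$direct_normal, 0)
  expect_gt(fc$diffuse_horizontal, 0)
  expect_error(solar_flux(30, 0, 1.2), "cloud")
})

test_that("hourly air temperature pins the extremes and is continuous", {
  tmin <- 10; tmax <- 24; rise <- 6.25
  expect_equal(hourly_air_temperature(tmin, tmax, rise, rise), tmin)
  expect_equal(hourly_air_temperature(tmin, tmax, rise, 13), tmax)
  # midway through the warming phase: the arithmetic mean
  expect_equal(hourly_air_temperature(tmin, tmax, rise, (rise + 13) / 2),
               (tmin + tmax) / 2, tolerance = 0.01)
  # continuity across midnight
  expect_equal(hourly_air_temperature(tmin, tmax, rise, 23.999),
               hourly_air_temperature(tmin, tmax, rise, 0.001),
               tolerance = 0.01)
  expect_error(hourly_air_temperature(24, 10, rise, 12), "tmin")
})

test_that("sky radiant temperature: overcast equals air, clear sits below", {
  expect_equal(sky_longwave(20, 50, cloud_frac = 1), 20, tolerance = 1e-6)
  expect_lt(sky_longwave(20, 50, cloud_frac = 0), 20)
  # monotone non-decreasing in air temperature at fixed cloud
  ts <- sky_longwave(seq(-10, 40, 5), 50, 0.3)
  expect_true(all(diff(ts) > 0))
})

test_that("ground surface balance closes and has the right forcing sign", {
  # night, isothermal: surface settles at air temperature
  g0 <- ground_surface_balance(0, 15, 15, 2, 15)
  expect_equal(g0$tground_c, 15, tolerance = 0.1)
  expect_lt(abs(g0$residual_Wm2), 1e-3)
  # clear noon: surface warmer than air
  g1 <- ground_surface_balance(800, 25, 5, 2, 20)
  expect_gt(g1$tground_c, 25)
  expect_lt(abs(g1$residual_Wm2), 1e-3)
})

test_that("log wind profile", {
  expect_equal(wind_profile(3, 2, 0.01, 2), 3)
  expect_equal(wind_profile(3, 2, 0.01, 0.01), 0)
  expect_equal(wind_profile(3, 2, 0.01, 1), 3 * log(100) / log(200),
               tolerance = 1e-9)
  expect_error(wind_profile(3, 2, 0.01, 0.001), "roughness")
})

test_that("build_day composes a physically consistent paired day", {
  site <- synthetic_site(30, seed = 3)
  d <- build_day(site, 7)
  expect_equal(nrow(d), 48)
  rec <- site$monthly[site$monthly$month == 7, ]
  # air temperatures within the monthly extremes
  expect_true(all(d$tair_c >= rec$tmin_C - 0.01))
  expect_true(all(d$tair_c <= rec$tmax_C + 0.01))
  # warming offset shifts every hour exactly
  d3 <- build_day(site, 7, warming_offset_C = 3)
  expect_equal(d3$tair_c, d$tair_c + 3, tolerance = 1e-9)
  # shade habitat: no direct beam; sun-patch ground hotter at noon
  sh <- d[d$habitat == "shade", ]
  su <- d[d$habitat == "sun", ]
  expect_true(all(sh$solar_direct_Wm2 == 0))
  expect_gte(su$tground_c[13], sh$tground_c[13])
  # daily direct-beam integral peaks at the June solstice above the tropic
  beam <- vapply(1:12, function(m) {
    dd <- build_day(site, m)
    sum(dd$solar_direct_Wm2[dd$habitat == "sun"])
  }, numeric(1))
  expect_equal(which.max(beam), 6)   # mid-June is closest to day 172
})

test_that("site climate validation and CSV round trip", {
  site <- synthetic_site(12, seed = 5)
  expect_error(site_climate(95, 0, 0, site$monthly), "latitude")
  bad <- site$monthly; bad$tmin_C[3] <- bad$tmax_C[3] + 1
  expect_error(site_climate(12, 0, 0, bad), "tmin")
  expect_error(site_climate(12, 0, 0, site$monthly[-1, ]), "exactly one")
  path <- withr::local_tempfile(fileext = ".csv")
  write_site_climate(site, path)
  back <- read_site_climate(path)
  expect_equal(back$latitude, site$latitude)
  expect_equal(back$monthly, site$monthly, tolerance = 1e-6)
})
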