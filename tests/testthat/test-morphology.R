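test_that("isometric scaling from the reference animal", {
  ref <- scale_morphology(682)
  expect_equal(ref$total_area_m2, 0.14 * 682 ^ 0.57, tolerance = 1e-9)
  expect_equal(ref$height_m, 1.473)
  # octuple mass: linear dims x2, areas x4
  big <- scale_morphology(8 * 682)
  expect_equal(big$parts$diameter_m, 2 * ref$parts$diameter_m)
  expect_equal(big$parts$area_m2, 4 * ref$parts$area_m2)
  # the downsized literature animal comes out ~135.7 cm tall
  small <- scale_morphology(533)
  expect_equal(small$height_m * 100, (533 / 682) ^ (1 / 3) * 147.3,
               tolerance = 1e-9)
  expect_equal(small$height_m, 1.357, tolerance = 0.001)
  expect_error(scale_morphology(-1), "positive")
  # part areas sum to the total; standing has no contact area
  expect_equal(sum(ref$parts$area_m2), ref$total_area_m2)
  expect_equal(ref$contact_area_m2, 0)
  expect_gt(scale_morphology(682, "lying")$contact_area_m2, 0)
})

test_that("surface-to-volume ratio strictly decreases with mass", {
  sv <- vapply(c(300, 500, 700, 900, 1200), function(m) {
    g <- scale_morphology(m)
    g$total_area_m2 / g$total_volume_m3
  }, numeric(1))
  expect_true(all(diff(sv) < 0))
})

test_that("convection coefficient: Hilpert band with free-convection floor", {
  # still air: positive free-convection floor
  expect_gt(convection_coefficient(0.6, 0, 20, 35), 0)
  # torso-sized cylinder at 1 m/s: single-digit h
  h1 <- convection_coefficient(0.6, 1, 20)
  expect_gt(h1, 6); expect_lt(h1, 8)
  # doubling wind in the 4e3-4e4 Reynolds band scales ~2^0.618
  ha <- convection_coefficient(0.3, 1, 20)
  hb <- convection_coefficient(0.3, 2, 20)
  expect_equal(hb / ha, 2 ^ 0.618, tolerance = 0.03)
  # thinner boundary layer on smaller parts
  expect_gt(convection_coefficient(0.1, 1, 20),
            convection_coefficient(0.6, 1, 20))
  # strictly increasing in wind
  hs <- convection_coefficient(0.4, seq(0.1, 5, 0.1), 20)
  expect_true(all(diff(hs) > 0))
  expect_error(convection_coefficient(-0.1, 1), "diameter")
})

test_that("silhouette projection geometry", {
  g <- scale_morphology(682)
  tor <- g$parts[g$parts$part == "torso", ]
  leg <- g$parts[g$parts$part == "leg1", ]
  s90 <- silhouette_area(g, 90)
  # broadside horizontal cylinder projects length x diameter
  expect_equal(unname(s90$by_part_m2["torso"]),
               tor$length_m * tor$diameter_m, tolerance = 1e-9)
  # overhead sun on a vertical leg: end-on disc
  s0 <- silhouette_area(g, 0)
  expect_equal(unname(s0$by_part_m2["leg1"]),
               pi * leg$diameter_m ^ 2 / 4, tolerance = 1e-9)
  # lying reduces the exposed silhouette
  gl <- scale_morphology(682, "lying")
  expect_lt(silhouette_area(gl, 60)$total_m2, silhouette_area(g, 60)$total_m2)
})
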