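test_that("characteristic length is 0.84 of the diameter and rejects nonpositive input", {
  expect_equal(characteristic_length(0.075), 0.063)
  expect_equal(characteristic_length(1), 0.84)
  expect_error(characteristic_length(0), "diameter")
  expect_error(characteristic_length(-0.1), "diameter")
})

test_that("boundary-layer conductance scales as the square root of wind speed", {
  d <- characteristic_length(0.075)
  expect_identical(boundary_layer_conductance(0, d), 0)
  # 1.4 * 0.135 * sqrt(1 / 0.063)
  expect_equal(boundary_layer_conductance(1, d), 0.75294, tolerance = 1e-4)
  for (u in c(0.5, 1, 2, 4)) {
    expect_equal(boundary_layer_conductance(4 * u, d),
                 2 * boundary_layer_conductance(u, d))
  }
  expect_error(boundary_layer_conductance(-1, d), "wind_speed")
})

test_that("absorbed radiation splits into short-wave and long-wave parts as specified", {
  w <- midday_weather()
  p <- psychrometric_state(w)
  scene <- scene_properties()
  geom <- illumination_geometry(1, 0.6)
  full <- absorbed_radiation(w, p, fruit_properties(albedo = 0.6), geom, scene)
  expect_equal(full$shortwave_net, 0.4 * 900)  # (1 - 0.6) * 900
  expect_equal(full$absorbed, full$shortwave_net + full$longwave_in)

  mirror <- absorbed_radiation(w, p, fruit_properties(albedo = 1), geom, scene)
  expect_equal(mirror$shortwave_net, 0)

  shaded <- absorbed_radiation(w, p, fruit_properties(),
                               illumination_geometry(0, 0.6), scene)
  expect_equal(shaded$shortwave_net, 0)
  expect_equal(shaded$absorbed, shaded$longwave_in)
  expect_true(all(c(full$absorbed, full$longwave_in, shaded$absorbed) > 0))
})

test_that("ground/leaf temperature falls back from scene to station to air", {
  p <- psychrometric_state(midday_weather())
  fr <- fruit_properties()
  geom <- illumination_geometry(0, 0.6)
  w_soil <- weather_sample(air_temp = 32, rel_humidity = 30, wind_speed = 3.5,
                           shortwave = 900, ground_temp = 45)
  base <- absorbed_radiation(midday_weather(), p, fr, geom,
                             scene_properties())
  soil <- absorbed_radiation(w_soil, p, fr, geom, scene_properties())
  pinned <- absorbed_radiation(w_soil, p, fr, geom,
                               scene_properties(ground_leaf_temp = 32))
  expect_gt(soil$longwave_in, base$longwave_in)  # hotter ground emits more
  expect_equal(pinned$longwave_in, base$longwave_in)
})

test_that("emitted radiation is grey-body and increasing in surface temperature", {
  expect_equal(emitted_radiation(25, 0), 0)
  # 0.95 * 5.67e-8 * 298^4
  expect_equal(emitted_radiation(25, 0.95), 424.84, tolerance = 1e-3)
  expect_gt(emitted_radiation(40, 0.95), emitted_radiation(30, 0.95))
})

test_that("sensible heat is linear and antisymmetric in the surface-air gradient", {
  expect_equal(sensible_heat(32, 32, 0.753), 0)
  expect_equal(sensible_heat(42, 32, 0.753), 29.3 * 0.753 * 10)
  for (delta in c(1, 5, 12)) {
    expect_equal(sensible_heat(32 + delta, 32, 0.5),
                 -sensible_heat(32 - delta, 32, 0.5))
  }
  expect_error(sensible_heat(40, 32, -0.1), "boundary_conductance")
})

test_that("linearized latent heat reproduces its limiting cases", {
  w <- midday_weather()
  p <- psychrometric_state(w)
  expect_equal(latent_heat(45, w, p, 0), 0)

  saturated <- midday_weather(rel_humidity = 100)
  p_sat <- psychrometric_state(saturated)
  expect_equal(latent_heat(32, saturated, p_sat, 5e-5), 0)

  # pure VPD term: T_fs = T_a so only lambda*g_w*rho*VPD/P remains
  p_fixed <- p
  p_fixed$air_density <- 1.14
  p_fixed$sat_vp_air <- 4.0
  p_fixed$actual_vp <- 4.0 - 3.33
  le <- latent_heat(32, w, p_fixed, 5e-5)
  expect_equal(le, 2.429e6 * 5e-5 * 1.14 * 3.33 / 101.3, tolerance = 1e-6)
})

test_that("energy residual populates all fluxes and satisfies its identities", {
  f <- energy_residual(40, canonical$weather, NULL, canonical$fruit,
                       canonical$geom, canonical$scene)
  expect_s3_class(f, "energy_fluxes")
  expect_equal(f$absorbed, f$shortwave_net + f$longwave_in)
  expect_equal(f$residual, f$absorbed - f$emitted - f$convective - f$latent)
  expect_gt(f$boundary_conductance, 0)
})

test_that("energy residual decreases strictly with surface temperature", {
  grid <- seq(canonical$weather$air_temp - 20,
              canonical$weather$air_temp + 40, by = 0.5)
  res <- vapply(grid, function(t) {
    energy_residual(t, canonical$weather, NULL, canonical$fruit,
                    canonical$geom, canonical$scene)$residual
  }, numeric(1))
  expect_true(all(diff(res) < 0))
})
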