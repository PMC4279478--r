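fixture_series <- function() {
  # three quarter-hours of the canonical midday conditions
  t0 <- as.POSIXct("2013-08-20 13:30:00", tz = "UTC")
  data.frame(timestamp = t0 + c(0, 900, 1800),
             air_temp = 32, rel_humidity = 30, wind_speed = 3.5,
             shortwave = 900, ground_temp = NA_real_, pressure = 101.3)
}

fixture_config <- function() simulation_config(levels = 1)

test_that("the identity perturbation changes nothing", {
  rep <- run_sensitivity(fixture_series(), fixture_config(),
                         perturbation_spec("albedo", values = 0))
  expect_true(all(rep$per_timestep$delta_fst == 0))
  expect_true(all(rep$summary$delta_fst == 0))
})

test_that("perturbation signs match the physics of each parameter", {
  w <- fixture_series()
  cfg <- fixture_config()
  # brighter emitter -> cooler fruit
  up_ef <- run_sensitivity(w, cfg, perturbation_spec("emissivity", 0.05))
  expect_true(all(up_ef$per_timestep$delta_fst < 0))
  # more reflective skin -> cooler; less reflective -> hotter
  alb <- run_sensitivity(w, cfg, perturbation_spec("albedo", c(-0.2, 0.2)))
  expect_true(all(alb$per_timestep$delta_fst[alb$per_timestep$perturbation
                                             < 0] > 0))
  expect_true(all(alb$per_timestep$delta_fst[alb$per_timestep$perturbation
                                             > 0] < 0))
  # more transpiration -> cooler, and shutting it off -> warmer
  gw <- run_sensitivity(w, cfg, perturbation_spec("vapour_conductance",
                                                  c(-1, 2)))
  d_off <- gw$summary$delta_fst[gw$summary$perturbation == -1]
  d_triple <- gw$summary$delta_fst[gw$summary$perturbation == 2]
  expect_true(all(d_off > 0))
  expect_true(all(d_triple < 0))
  expect_true(all(d_triple < d_off))
})

test_that("relative perturbations are multiplicative on the reference value", {
  rep <- run_sensitivity(fixture_series(), fixture_config(),
                         perturbation_spec("emissivity", c(-0.05, 0.05)))
  expect_equal(sort(unique(rep$summary$perturbed_value)),
               c(0.95 * 0.95, 0.95 * 1.05))
  abs_rep <- run_sensitivity(fixture_series(), fixture_config(),
                             perturbation_spec("vapour_conductance", 1.5e-4,
                                               mode = "absolute"))
  expect_equal(unique(abs_rep$summary$perturbed_value), 1.5e-4)
  expect_error(
    run_sensitivity(fixture_series(), fixture_config(),
                    perturbation_spec("emissivity", 0.2)),
    "emissivity")
})

test_that("the illumination grid decreases from the sunlit reference", {
  # A_r/A' pinned so only the sunlit fraction varies
  cfg <- simulation_config(levels = 1, reflected_ratio = 0.6)
  grid <- illumination_grid(fixture_series(), cfg,
                            levels = c(1, 0.8, 0.6, 0.5, 0.4, 0.2, 0))
  s <- grid$summary[grid$summary$summary_kind == "daily_max", ]
  s <- s[order(-s$perturbed_value), ]
  expect_equal(s$delta_fst[s$perturbed_value == 1], 0)
  expect_true(all(diff(s$delta_fst) < 0))  # monotone in decreasing level

  # under the level-dependent default, half-sunlit fruit sees less
  # reflected radiation (A_r/A' 0.3) and dips below the pinned run
  expect_equal(default_reflected_ratio(c(1, 0.5, 0)), c(0.6, 0.3, 0.6))
  free <- illumination_grid(fixture_series(), fixture_config(),
                            levels = c(1, 0.5))
  pinned <- grid$summary
  d_free <- free$summary$delta_fst[free$summary$perturbed_value == 0.5 &
                                     free$summary$summary_kind == "midday"]
  d_pin <- pinned$delta_fst[pinned$perturbed_value == 0.5 &
                              pinned$summary_kind == "midday"]
  expect_lt(d_free[1], d_pin[1])
})

test_that("illumination steps are nearly equal at fixed reflected ratio", {
  cfg <- simulation_config(levels = 1, reflected_ratio = 0.6)
  grid <- illumination_grid(fixture_series(), cfg,
                            levels = c(1, 0.8, 0.6, 0.4, 0.2, 0))
  s <- grid$summary[grid$summary$summary_kind == "midday", ]
  s <- s[order(-s$perturbed_value), ]
  steps <- -diff(s$delta_fst)
  # the short-wave term is linear in A_d/A, so equal level steps give
  # near-equal temperature steps (the T^4 emission bends them slightly)
  expect_lt(max(steps) - min(steps), 0.15)
})

test_that("temperature response to illumination scales linearly with solar input", {
  deltas <- vapply(c(200, 600, 1000), function(rs) {
    w <- midday_weather(shortwave = rs)
    s1 <- solve_fst(w, fruit_properties(), illumination_geometry(1, 0.6))
    s0 <- solve_fst(w, fruit_properties(), illumination_geometry(0.8, 0.6))
    s1$surface_temp - s0$surface_temp
  }, numeric(1))
  expect_equal(deltas[2] / deltas[1], 3, tolerance = 0.15)
  expect_equal(deltas[3] / deltas[1], 5, tolerance = 0.25)
})
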