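eq_series <- function(n = 8, air_temp = 25) {
  t0 <- as.POSIXct("2013-08-20 11:00:00", tz = "UTC")
  data.frame(timestamp = t0 + seq(0, by = 900, length.out = n),
             air_temp = air_temp, rel_humidity = 100, wind_speed = 2,
             shortwave = 0, ground_temp = NA_real_, pressure = 101.3)
}

eq_config <- function(levels = 0) {
  simulation_config(levels = levels, reflected_ratio = 0,
                    scene = scene_properties(atm_emissivity_model = "fixed",
                                             atm_emissivity_value = 0.95))
}

test_that("equilibrium weather yields a flat series at air temperature", {
  sim <- run_timeseries(eq_series(), eq_config())
  expect_true(all(sim$converged))
  expect_equal(sim$fst, sim$air_temp, tolerance = 1e-3)
  expect_equal(fst_air_difference(sim)$fst_minus_air, rep(0, nrow(sim)),
               tolerance = 1e-3)
})

test_that("a clear-sky day peaks near solar maximum and respects level ordering", {
  # steady wind isolates the radiative timing (gusts can shift the peak)
  w <- generate_synthetic(synthetic_weather_spec(seed = 42,
                                                 wind_jitter_sd = 0))
  sim <- run_timeseries(w, simulation_config(levels = c(1, 0),
                                             apply_window = FALSE))
  expect_true(all(sim$converged))
  expect_equal(nrow(sim), nrow(w) * 2)

  sunlit <- sim[sim$level == 1, ]
  shaded <- sim[sim$level == 0, ]
  # fully sunlit fruit is at least as hot as shaded fruit at every step
  expect_true(all(sunlit$fst >= shaded$fst - 1e-9))
  # the surface-air excess peaks within an hour of peak solar radiation
  t_peak_rs <- w$timestamp[which.max(w$shortwave)]
  t_peak_dt <- sunlit$timestamp[which.max(sunlit$fst_minus_air)]
  expect_lte(abs(as.numeric(t_peak_dt) - as.numeric(t_peak_rs)), 3600)
})

test_that("the daily reporting window filters rows unless disabled", {
  w <- generate_synthetic(synthetic_weather_spec(seed = 3))
  windowed <- run_timeseries(w, simulation_config(levels = 1))
  full <- run_timeseries(w, simulation_config(levels = 1,
                                              apply_window = FALSE))
  hrs <- as.numeric(format(windowed$timestamp, "%H"))
  expect_true(all(hrs >= 11 & hrs <= 18))
  expect_lt(nrow(windowed), nrow(full))
  expect_equal(nrow(windowed), sum(
    as.numeric(format(w$timestamp, "%H")) * 60 +
      as.numeric(format(w$timestamp, "%M")) >= 11 * 60 &
    as.numeric(format(w$timestamp, "%H")) * 60 +
      as.numeric(format(w$timestamp, "%M")) <= 18 * 60))
})

test_that("simulation is deterministic and rejects bad input series", {
  w <- generate_synthetic(synthetic_weather_spec(seed = 11))
  cfg <- simulation_config(levels = c(1, 0.5))
  expect_identical(run_timeseries(w, cfg), run_timeseries(w, cfg))

  shuffled <- w[rev(seq_len(nrow(w))), ]
  expect_error(run_timeseries(shuffled, cfg), "increasing")
  expect_error(run_timeseries(w[0, ], cfg), "no weather rows|missing")

  holey <- w
  holey$air_temp[20] <- NA
  expect_warning(run_timeseries(holey, simulation_config(
    levels = 1, apply_window = FALSE)), "missing weather fields")
})

test_that("flux decomposition uses gain-positive signs and sums to the residual", {
  w <- generate_synthetic(synthetic_weather_spec(seed = 42))
  sim <- run_timeseries(w, simulation_config(levels = 1))
  dec <- flux_decomposition(sim)
  total <- dec$r_abs + dec$minus_r_e + dec$minus_h + dec$minus_le
  expect_true(all(abs(total) < 0.01))
  expect_true(all(dec$r_abs > 0))
  expect_true(all(dec$minus_r_e < 0))
  # transpiration is the minor flux at midday: smaller than convection
  # and far smaller than the radiative input
  midday <- format(dec$timestamp, "%H:%M") == "14:00"
  expect_true(all(abs(dec$minus_le[midday]) < abs(dec$minus_h[midday])))
  expect_true(all(abs(dec$minus_le[midday]) < dec$r_abs[midday]))
})

test_that("night-like records have zero net short-wave input", {
  night <- data.frame(
    timestamp = as.POSIXct("2013-08-20 23:00:00", tz = "UTC") +
      c(0, 900, 1800),
    air_temp = 18, rel_humidity = 70, wind_speed = 1.5, shortwave = 0,
    ground_temp = NA_real_, pressure = 101.3)
  sim <- run_timeseries(night, simulation_config(levels = 1,
                                                 apply_window = FALSE))
  expect_true(all(sim$r_ns == 0))
  expect_true(all(sim$converged))
})

test_that("simulation output round-trips as delimited text", {
  w <- generate_synthetic(synthetic_weather_spec(seed = 8))
  sim <- run_timeseries(w, simulation_config(levels = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_simulation(sim, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(sim))
  expect_equal(back$fst, sim$fst, tolerance = 1e-9)
  expect_true(all(back$converged))
})
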