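# Shared fixtures and an independent brute-force oracle for the surface
# energy balance. The oracle evaluates every flux straight from the published
# formulas (it never calls the package's flux functions) and locates the
# balance temperature by exhaustive grid search.

midday_weather <- function(air_temp = 32, rel_humidity = 30,
                           wind_speed = 3.5, shortwave = 900,
                           pressure = 101.3) {
  weather_sample(air_temp = air_temp, rel_humidity = rel_humidity,
                 wind_speed = wind_speed, shortwave = shortwave,
                 pressure = pressure)
}

# canonical hot clear midday: Ta 32 degC, RH 30 %, u 3.5 m/s, Rs 900 W/m2,
# apple at reference optical/thermal properties, fully sunlit
canonical <- list(
  weather = midday_weather(),
  fruit = fruit_properties(diameter = 0.075, albedo = 0.6,
                           emissivity = 0.95, vapour_conductance = 5e-5),
  geom = illumination_geometry(1, 0.6),
  scene = scene_properties(ground_emissivity = 0.95,
                           atm_emissivity_model = "brutsaert")
)

# vectorized residual from first principles (Tetens, Brutsaert, ideal gas)
oracle_residual <- function(t_fs, w, fruit, geom, scene) {
  sigma <- 5.67e-8
  es <- function(t) 0.611 * exp(17.502 * t / (t + 240.97))
  es_a <- es(w$air_temp)
  e_a <- es_a * w$rel_humidity / 100
  delta <- es_a * 17.502 * 240.97 / (w$air_temp + 240.97)^2
  rho <- 1000 * w$pressure / (287.04 * (w$air_temp + 273.15))
  eps_a <- switch(scene$atm_emissivity_model,
    brutsaert = 1.24 * (10 * e_a / (w$air_temp + 273.15))^(1 / 7),
    quadratic_clear_sky = 9.2e-6 * (w$air_temp + 273.15)^2,
    fixed = scene$atm_emissivity_value)
  t_g <- if (!is.na(scene$ground_leaf_temp)) scene$ground_leaf_temp
         else if (!is.null(w$ground_temp) && !is.na(w$ground_temp)) {
           w$ground_temp
         } else w$air_temp
  r_abs <- geom$sunlit_ratio * (1 - fruit$albedo) * w$shortwave +
    eps_a * sigma * (w$air_temp + 273)^4 +
    geom$reflected_ratio * scene$ground_emissivity * sigma * (t_g + 273)^4
  g_a <- 1.4 * 0.135 * sqrt(w$wind_speed / (0.84 * fruit$diameter))
  r_e <- fruit$emissivity * sigma * (t_fs + 273)^4
  h <- 29.3 * g_a * (t_fs - w$air_temp)
  coef <- 2.429e6 * fruit$vapour_conductance * rho / w$pressure
  le <- coef * delta * (t_fs - w$air_temp) + coef * (es_a - e_a)
  r_abs - r_e - h - le
}

# exhaustive argmin |residual| over a fine temperature grid
oracle_fst <- function(w, fruit, geom, scene, spacing = 0.001) {
  grid <- seq(w$air_temp - 20, w$air_temp + 40, by = spacing)
  res <- oracle_residual(grid, w, fruit, geom, scene)
  grid[which.min(abs(res))]
}

# weather + scene constructed so the balance closes exactly at air
# temperature: saturated air, no sun, sky emissivity equal to the fruit's,
# no reflected ground term
equilibrium_case <- function(air_temp = 25, wind_speed = 2) {
  list(
    weather = weather_sample(air_temp = air_temp, rel_humidity = 100,
                             wind_speed = wind_speed, shortwave = 0),
    fruit = fruit_properties(),
    geom = illumination_geometry(0, 0),
    scene = scene_properties(atm_emissivity_model = "fixed",
                             atm_emissivity_value = 0.95)
  )
}

# randomized physically plausible weather/fruit/scene draws
random_case <- function() {
  w <- midday_weather(
    air_temp = stats::runif(1, 15, 40),
    rel_humidity = stats::runif(1, 10, 95),
    wind_speed = stats::runif(1, 0.3, 8),
    shortwave = stats::runif(1, 0, 1100)
  )
  fruit <- fruit_properties(
    diameter = stats::runif(1, 0.05, 0.1),
    albedo = stats::runif(1, 0.4, 0.8),
    emissivity = stats::runif(1, 0.9, 1),
    vapour_conductance = stats::runif(1, 0, 1.5e-4)
  )
  geom <- illumination_geometry(sample(c(0, 0.2, 0.4, 0.5, 0.6, 0.8, 1), 1))
  list(weather = w, fruit = fruit, geom = geom,
       scene = scene_properties())
}

solve_case <- function(case, ...) {
  solve_fst(case$weather, case$fruit, case$geom, case$scene, ...)
}
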