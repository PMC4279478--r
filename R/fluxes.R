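#' Characteristic length of the fruit
#'
#' Effective dimension of the fruit treated as a sphere in cross-flow:
#' 0.84 times the diameter.
#'
#' @param diameter Fruit diameter, m (> 0).
#' @return Characteristic length d, m.
#' @export
#' @examples
#' characteristic_length(0.075)  # 0.063 m
characteristic_length <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be > 0 m", call. = FALSE)
  .const$shape_factor * diameter
}

#' Boundary-layer conductance for turbulent sensible-heat exchange
#'
#' Molar conductance between the fruit surface and the air for forced
#' convection, `g_a = 1.4 * 0.135 * sqrt(u / d)`. The factor 1.4 is the
#' empirical outdoor-turbulence enhancement. Still air gives zero
#' conductance: only forced convection is modelled.
#'
#' @param wind_speed Wind speed u, m/s (>= 0).
#' @param char_length Characteristic length d, m (> 0), from
#'   [characteristic_length()].
#' @return Conductance g_a, mol m-2 s-1.
#' @export
#' @examples
#' boundary_layer_conductance(1, characteristic_length(0.075))  # ~0.753
boundary_layer_conductance <- function(wind_speed, char_length) {
  if (any(wind_speed < 0)) stop("wind_speed must be >= 0 m/s", call. = FALSE)
  if (any(char_length <= 0)) stop("char_length must be > 0 m", call. = FALSE)
  .const$outdoor_factor * .const$conductance_coeff *
    sqrt(wind_speed / char_length)
}

#' Short-wave, long-wave and total absorbed radiation
#'
#' Net absorbed short-wave radiation scales with the sunlit-area ratio and
#' the fruit reflectance: `R_ns = (A_d/A) (1 - albedo) R_s`. Incoming
#' long-wave radiation sums sky emission and ground/canopy emission
#' intercepted over the reflected-area ratio:
#' `R_nl = eps_a sigma (T_a + 273)^4 + (A_r/A') eps_g sigma (T_gmean + 273)^4`.
#'
#' @param weather A single weather record.
#' @param psychro The matching [psychrometric_state()].
#' @param fruit [fruit_properties()].
#' @param geom [illumination_geometry()].
#' @param scene [scene_properties()].
#' @return List with `shortwave_net`, `longwave_in` and `absorbed`
#'   (`= shortwave_net + longwave_in`), all W m-2.
#' @export
absorbed_radiation <- function(weather, psychro, fruit, geom, scene) {
  sigma <- .const$stefan_boltzmann
  k <- .const$kelvin_offset_rad
  eps_a <- atmospheric_emissivity(weather$air_temp, psychro$actual_vp,
                                  model = scene$atm_emissivity_model,
                                  fixed_value = scene$atm_emissivity_value)
  t_g <- resolve_ground_temp(weather, scene)
  r_ns <- geom$sunlit_ratio * (1 - fruit$albedo) * weather$shortwave
  r_nl <- eps_a * sigma * (weather$air_temp + k)^4 +
    geom$reflected_ratio * scene$ground_emissivity * sigma * (t_g + k)^4
  list(shortwave_net = r_ns, longwave_in = r_nl, absorbed = r_ns + r_nl)
}

#' Long-wave radiation emitted by the fruit surface
#'
#' Grey-body emission `R_e = eps_f sigma (T_fs + 273)^4`.
#'
#' @param surface_temp Fruit surface temperature T_fs, degC.
#' @param emissivity Fruit emissivity eps_f in `(0, 1]` (0 allowed only as a
#'   boundary probe).
#' @return Emitted radiation, W m-2.
#' @export
#' @examples
#' emitted_radiation(25, 0.95)  # ~424.9 W/m2
emitted_radiation <- function(surface_temp, emissivity) {
  emissivity * .const$stefan_boltzmann *
    (surface_temp + .const$kelvin_offset_rad)^4
}

#' Sensible heat exchanged by forced convection
#'
#' `H = c_p g_a (T_fs - T_a)`: positive when the surface is warmer than the
#' air (the fruit loses heat).
#'
#' @param surface_temp Fruit surface temperature, degC.
#' @param air_temp Air temperature, degC.
#' @param boundary_conductance g_a, mol m-2 s-1.
#' @return Sensible heat flux H, W m-2.
#' @export
sensible_heat <- function(surface_temp, air_temp, boundary_conductance) {
  if (any(boundary_conductance < 0)) {
    stop("boundary_conductance must be >= 0", call. = FALSE)
  }
  .const$cp_air_molar * boundary_conductance * (surface_temp - air_temp)
}

#' Latent heat lost by transpiration (linearized)
#'
#' The transpirational flux driven by the surface-to-air vapour pressure
#' difference, linearized around air temperature:
#' `lambda E = lambda g_w rho_air Delta (T_fs - T_a) / P +
#'  lambda g_w rho_air (e_s(T_a) - e_a) / P`.
#' The second term is the vapour-pressure-deficit contribution; the first
#' grows with surface warming. Zero skin conductance gives zero flux.
#'
#' @param surface_temp Fruit surface temperature, degC.
#' @param weather A single weather record (supplies air temperature and
#'   pressure).
#' @param psychro The matching [psychrometric_state()].
#' @param vapour_conductance Skin conductance to water vapour g_w, m/s.
#' @return Latent heat flux, W m-2.
#' @export
latent_heat <- function(surface_temp, weather, psychro, vapour_conductance) {
  if (any(vapour_conductance < 0)) {
    stop("vapour_conductance must be >= 0 m/s", call. = FALSE)
  }
  p <- weather$pressure %||% 101.3
  coef <- .const$latent_heat_vap * vapour_conductance * psychro$air_density / p
  coef * psychro$svp_slope * (surface_temp - weather$air_temp) +
    coef * (psychro$sat_vp_air - psychro$actual_vp)
}

#' Energy-balance residual and component fluxes at a trial surface temperature
#'
#' Evaluates every term of the steady-state surface balance
#' `R_abs = R_e + H + lambda E` at the given surface temperature and returns
#' the residual `R_abs - R_e - H - lambda E`. The residual is strictly
#' decreasing in surface temperature (every loss term grows with it), so it
#' has a unique root: the fruit surface temperature.
#'
#' @inheritParams absorbed_radiation
#' @param surface_temp Trial surface temperature, degC.
#' @param psychro Optional precomputed [psychrometric_state()]; computed from
#'   `weather` when `NULL`.
#' @return An object of class `energy_fluxes`: list with `absorbed`,
#'   `shortwave_net`, `longwave_in`, `emitted`, `convective`, `latent`
#'   (all W m-2), `boundary_conductance` (mol m-2 s-1) and `residual` (W m-2).
#' @export
energy_residual <- function(surface_temp, weather, psychro = NULL, fruit,
                            geom, scene) {
  if (is.null(psychro)) psychro <- psychrometric_state(weather)
  g_a <- boundary_layer_conductance(weather$wind_speed,
                                    characteristic_length(fruit$diameter))
  rad <- absorbed_radiation(weather, psychro, fruit, geom, scene)
  r_e <- emitted_radiation(surface_temp, fruit$emissivity)
  h <- sensible_heat(surface_temp, weather$air_temp, g_a)
  le <- latent_heat(surface_temp, weather, psychro, fruit$vapour_conductance)
  structure(list(
    absorbed = rad$absorbed,
    shortwave_net = rad$shortwave_net,
    longwave_in = rad$longwave_in,
    emitted = r_e,
    convective = h,
    latent = le,
    boundary_conductance = g_a,
    residual = rad$absorbed - r_e - h - le
  ), class = "energy_fluxes")
}
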