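#' Saturation vapour pressure of water (Tetens form)
#'
#' Computes the saturation vapour pressure of air over liquid water,
#' `e_s(T) = 0.611 * exp(17.502 * T / (T + 240.97))` kPa, the standard
#' agrometeorological Tetens formulation.
#'
#' @param temp Temperature in degrees Celsius, in `[-20, 60]`. Vectorised.
#' @return Saturation vapour pressure in kPa.
#' @export
#' @examples
#' saturation_vapour_pressure(20)   # ~2.337 kPa
#' saturation_vapour_pressure(0)    # 0.611 kPa
saturation_vapour_pressure <- function(temp) {
  check_temp_range(temp)
  0.611 * exp(17.502 * temp / (temp + 240.97))
}

#' Slope of the saturation vapour pressure curve
#'
#' Analytic derivative of [saturation_vapour_pressure()] with respect to
#' temperature, used to linearize the latent-heat flux around air temperature.
#'
#' @inheritParams saturation_vapour_pressure
#' @return Slope in kPa per degree Celsius (always positive).
#' @export
#' @examples
#' svp_slope(20)  # ~0.145 kPa/degC
svp_slope <- function(temp) {
  check_temp_range(temp)
  es <- 0.611 * exp(17.502 * temp / (temp + 240.97))
  es * 17.502 * 240.97 / (temp + 240.97)^2
}

check_temp_range <- function(temp, lower = -20, upper = 60) {
  if (any(!is.finite(temp)) || any(temp < lower) || any(temp > upper)) {
    stop(sprintf("temperature must lie in [%g, %g] degC", lower, upper),
         call. = FALSE)
  }
  invisible(temp)
}

#' Dry-air density from the ideal gas law
#'
#' @param temp Air temperature in degrees Celsius.
#' @param pressure Barometric pressure in kPa (must be positive).
#' @return Air density in kg m-3.
#' @export
#' @examples
#' air_density(25, 101.3)  # ~1.184 kg/m3
air_density <- function(temp, pressure) {
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop("pressure must be positive (kPa)", call. = FALSE)
  }
  1000 * pressure / (.const$r_dry_air * (temp + .const$kelvin_offset))
}

#' Dew point temperature (inverse Tetens)
#'
#' @param actual_vp Actual vapour pressure in kPa (positive).
#' @return Dew point in degrees Celsius.
#' @export
dew_point <- function(actual_vp) {
  if (any(actual_vp <= 0)) stop("actual_vp must be positive", call. = FALSE)
  x <- log(actual_vp / 0.611)
  240.97 * x / (17.502 - x)
}

#' Clear-sky atmospheric emissivity
#'
#' Effective grey-body emissivity of a cloudless atmosphere used for the
#' incoming long-wave radiation term. Three models are offered:
#' `"brutsaert"` (default), `e_a`-dependent: `1.24 * (10 e_a / T_K)^(1/7)`
#' with `e_a` in kPa (the factor 10 converts to hPa); `"quadratic_clear_sky"`:
#' `9.2e-6 * T_K^2`; and `"fixed"`: a user-supplied constant.
#'
#' @param air_temp Air temperature in degrees Celsius.
#' @param actual_vp Actual vapour pressure in kPa (ignored by the
#'   temperature-only models).
#' @param model One of `"brutsaert"`, `"quadratic_clear_sky"`, `"fixed"`.
#' @param fixed_value Emissivity in (0, 1] used when `model = "fixed"`.
#' @return Dimensionless emissivity in (0, 1].
#' @export
#' @examples
#' atmospheric_emissivity(32, 1.43)                      # ~0.80
#' atmospheric_emissivity(32, model = "quadratic_clear_sky")
atmospheric_emissivity <- function(air_temp, actual_vp = NULL,
                                   model = c("brutsaert",
                                             "quadratic_clear_sky",
                                             "fixed"),
                                   fixed_value = NULL) {
  if (length(model) != 1 || !model %in%
        c("brutsaert", "quadratic_clear_sky", "fixed")) {
    model <- tryCatch(match.arg(model),
                      error = function(e)
                        stop("unknown atmospheric emissivity model: ",
                             paste(model, collapse = "/"), call. = FALSE))
  }
  t_k <- air_temp + .const$kelvin_offset
  eps <- switch(model,
    brutsaert = {
      if (is.null(actual_vp) || any(actual_vp < 0)) {
        stop("brutsaert model needs actual_vp >= 0 (kPa)", call. = FALSE)
      }
      1.24 * (10 * actual_vp / t_k)^(1 / 7)
    },
    quadratic_clear_sky = 9.2e-6 * t_k^2,
    fixed = {
      if (is.null(fixed_value) || any(fixed_value <= 0) ||
            any(fixed_value > 1)) {
        stop("fixed emissivity model needs a value in (0, 1]", call. = FALSE)
      }
      fixed_value
    })
  pmin(eps, 1)
}

#' Psychrometric state of the air
#'
#' Derives the humidity-related quantities the latent-heat flux needs from a
#' weather record: saturation and actual vapour pressure, the slope of the
#' saturation curve at the chosen linearization temperature, and air density.
#'
#' @param weather A single weather record (see [weather_sample()]) or any list
#'   with `air_temp`, `rel_humidity` and `pressure` fields.
#' @param slope_at Where to evaluate the saturation-curve slope: `"air"`
#'   (default, the linearization point of the flux expansion) or `"dewpoint"`.
#' @return An object of class `psychrometric_state`: list with `sat_vp_air`
#'   (kPa), `actual_vp` (kPa), `svp_slope` (kPa/degC), `air_density` (kg/m3).
#' @export
#' @examples
#' w <- weather_sample(air_temp = 32, rel_humidity = 30, wind_speed = 3.5,
#'                     shortwave = 900)
#' psychrometric_state(w)
psychrometric_state <- function(weather, slope_at = c("air", "dewpoint")) {
  slope_at <- match.arg(slope_at)
  es <- saturation_vapour_pressure(weather$air_temp)
  ea <- es * weather$rel_humidity / 100
  t_slope <- if (slope_at == "air") weather$air_temp else dew_point(ea)
  out <- list(
    sat_vp_air  = es,
    actual_vp   = ea,
    svp_slope   = svp_slope(t_slope),
    air_density = air_density(weather$air_temp,
                              weather$pressure %||% 101.3)
  )
  class(out) <- "psychrometric_state"
  out
}
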