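#' A single weather record
#'
#' Constructs and validates one weather observation, the forcing for all
#' surface fluxes. Series are ordinary data frames whose columns carry the
#' same names; [validate_weather()] checks a whole series.
#'
#' @param timestamp POSIXct timestamp (optional for single-record use).
#' @param air_temp Air temperature, degC.
#' @param rel_humidity Relative humidity, percent in `[0, 100]`.
#' @param wind_speed Wind speed, m/s, non-negative.
#' @param shortwave Incoming short-wave (solar) radiation, W m-2, non-negative.
#' @param ground_temp Optional soil/ground temperature, degC (`NA` = use air
#'   temperature for the surrounding ground and leaves).
#' @param pressure Barometric pressure, kPa (default 101.3).
#' @return A one-row `data.frame` of class `weather_sample`.
#' @export
#' @examples
#' weather_sample(air_temp = 32, rel_humidity = 30, wind_speed = 3.5,
#'                shortwave = 900)
weather_sample <- function(timestamp = as.POSIXct(NA), air_temp, rel_humidity,
                           wind_speed, shortwave, ground_temp = NA_real_,
                           pressure = 101.3) {
  out <- data.frame(timestamp = timestamp, air_temp = air_temp,
                    rel_humidity = rel_humidity, wind_speed = wind_speed,
                    shortwave = shortwave, ground_temp = ground_temp,
                    pressure = pressure)
  validate_weather(out)
  class(out) <- c("weather_sample", "data.frame")
  out
}

#' Validate a weather series
#'
#' Checks column presence and the physical invariants of each record:
#' relative humidity in `[0, 100]`, non-negative wind and short-wave
#' radiation, positive pressure.
#'
#' @param weather A data frame with the [weather_sample()] columns.
#' @param required Columns that must be present.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_weather <- function(weather,
                             required = c("air_temp", "rel_humidity",
                                          "wind_speed", "shortwave")) {
  missing_cols <- setdiff(required, names(weather))
  if (length(missing_cols)) {
    stop("weather series is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- function(cond, msg) if (any(cond, na.rm = TRUE)) stop(msg, call. = FALSE)
  bad(weather$rel_humidity < 0 | weather$rel_humidity > 100,
      "rel_humidity must lie in [0, 100] %")
  bad(weather$wind_speed < 0, "wind_speed must be >= 0 m/s")
  bad(weather$shortwave < 0, "shortwave must be >= 0 W/m2")
  if (!is.null(weather$pressure)) {
    bad(weather$pressure <= 0, "pressure must be > 0 kPa")
  }
  invisible(weather)
}

#' Optical and thermal properties of the fruit
#'
#' Defaults are the reference values for a mature apple: diameter 0.075 m,
#' short-wave reflectance (albedo) 0.6, long-wave emissivity 0.95 and a skin
#' conductance to water vapour of 5e-5 m/s.
#'
#' @param diameter Fruit diameter, m (> 0).
#' @param albedo Short-wave reflectance in `[0, 1]`.
#' @param emissivity Long-wave emissivity in `(0, 1]`.
#' @param vapour_conductance Skin conductance to water vapour, m/s (>= 0).
#' @return An object of class `fruit_properties`.
#' @export
#' @examples
#' fruit_properties()                       # apple reference values
#' fruit_properties(albedo = 0.48)          # darker skin
fruit_properties <- function(diameter = 0.075, albedo = 0.6,
                             emissivity = 0.95, vapour_conductance = 5e-5) {
  if (diameter <= 0) stop("diameter must be > 0 m", call. = FALSE)
  if (albedo < 0 || albedo > 1) stop("albedo must lie in [0, 1]", call. = FALSE)
  if (emissivity <= 0 || emissivity > 1) {
    stop("emissivity must lie in (0, 1]", call. = FALSE)
  }
  if (vapour_conductance < 0) {
    stop("vapour_conductance must be >= 0 m/s", call. = FALSE)
  }
  structure(list(diameter = diameter, albedo = albedo, emissivity = emissivity,
                 vapour_conductance = vapour_conductance),
            class = "fruit_properties")
}

#' Illumination geometry of the fruit
#'
#' `sunlit_ratio` is the ratio of the projected sunlit surface area in the
#' direction of the incident sunlight to the maximum projected area (1 =
#' fully sunlit, 0 = fully shaded by leaves). `reflected_ratio` is the
#' empirical ratio of the area receiving ground/canopy-reflected radiation to
#' the total fruit surface area; when `NULL` it follows
#' [default_reflected_ratio()].
#'
#' @param sunlit_ratio A_d/A in `[0, 1]`.
#' @param reflected_ratio A_r/A' in `[0, reflected_max]`, or `NULL` for the
#'   illumination-dependent default.
#' @param reflected_max Upper bound on the reflected ratio (default 0.6).
#' @return An object of class `illumination_geometry`.
#' @export
#' @examples
#' illumination_geometry(1)            # fully sunlit, A_r/A' = 0.6
#' illumination_geometry(0.5)          # half sunlit,  A_r/A' = 0.3
illumination_geometry <- function(sunlit_ratio = 1, reflected_ratio = NULL,
                                  reflected_max = 0.6) {
  if (sunlit_ratio < 0 || sunlit_ratio > 1) {
    stop("sunlit_ratio (A_d/A) must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(reflected_ratio)) {
    reflected_ratio <- default_reflected_ratio(sunlit_ratio)
  }
  if (reflected_ratio < 0 || reflected_ratio > reflected_max) {
    stop(sprintf("reflected_ratio (A_r/A') must lie in [0, %g]", reflected_max),
         call. = FALSE)
  }
  structure(list(sunlit_ratio = sunlit_ratio,
                 reflected_ratio = reflected_ratio),
            class = "illumination_geometry")
}

#' Default reflected-radiation ratio for an illumination level
#'
#' The reflected-area ratio A_r/A' pairs empirically with the illumination
#' level: 0.6 for fully sunlit fruit, 0.3 for half-sunlit fruit, 0.6 for
#' fully shaded fruit; all other levels default to 0.6.
#'
#' @param sunlit_ratio A_d/A in `[0, 1]` (vectorised).
#' @return The default A_r/A' for each level.
#' @export
default_reflected_ratio <- function(sunlit_ratio) {
  ifelse(abs(sunlit_ratio - 0.5) < 1e-9, 0.3, 0.6)
}

#' Radiative properties of the fruit's surroundings
#'
#' @param ground_emissivity Long-wave emissivity of the surrounding ground
#'   and foliage, `(0, 1]` (default 0.95).
#' @param ground_leaf_temp Mean temperature of the surrounding ground and
#'   leaves, degC. `NA` (default) falls back, per record, to the weather
#'   series' `ground_temp` if present, else to air temperature.
#' @param atm_emissivity_model Clear-sky atmospheric emissivity model, see
#'   [atmospheric_emissivity()].
#' @param atm_emissivity_value Constant emissivity used when the model is
#'   `"fixed"`.
#' @return An object of class `scene_properties`.
#' @export
scene_properties <- function(ground_emissivity = 0.95,
                             ground_leaf_temp = NA_real_,
                             atm_emissivity_model = c("brutsaert",
                                                      "quadratic_clear_sky",
                                                      "fixed"),
                             atm_emissivity_value = NULL) {
  atm_emissivity_model <- match.arg(atm_emissivity_model)
  if (ground_emissivity <= 0 || ground_emissivity > 1) {
    stop("ground_emissivity must lie in (0, 1]", call. = FALSE)
  }
  if (atm_emissivity_model == "fixed" &&
        (is.null(atm_emissivity_value) || atm_emissivity_value <= 0 ||
           atm_emissivity_value > 1)) {
    stop("fixed atmospheric emissivity requires a value in (0, 1]",
         call. = FALSE)
  }
  structure(list(ground_emissivity = ground_emissivity,
                 ground_leaf_temp = ground_leaf_temp,
                 atm_emissivity_model = atm_emissivity_model,
                 atm_emissivity_value = atm_emissivity_value),
            class = "scene_properties")
}

# mean ground/leaf temperature for a record: explicit scene value wins,
# then the station's ground_temp, then air temperature
resolve_ground_temp <- function(weather, scene) {
  if (!is.null(scene$ground_leaf_temp) && !is.na(scene$ground_leaf_temp)) {
    return(scene$ground_leaf_temp)
  }
  gt <- weather$ground_temp
  if (!is.null(gt) && !all(is.na(gt))) {
    return(ifelse(is.na(gt), weather$air_temp, gt))
  }
  weather$air_temp
}
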