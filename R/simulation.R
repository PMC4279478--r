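#' Configuration for a time-series simulation
#'
#' @param levels Illumination levels A_d/A to run, each in `[0, 1]`.
#' @param fruit [fruit_properties()].
#' @param scene [scene_properties()].
#' @param reflected_ratio A_r/A' applied at every level, or `NULL` for the
#'   level-dependent default ([default_reflected_ratio()]).
#' @param time_step Nominal step of the weather series, minutes.
#' @param window_start,window_end Daily clock window reported on
#'   (defaults "11:00"-"18:00", the hours over which sunburn develops).
#' @param apply_window If `FALSE` every time step is reported.
#' @param solver [solver_config()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(levels = 1, fruit = fruit_properties(),
                              scene = scene_properties(),
                              reflected_ratio = NULL, time_step = 15,
                              window_start = "11:00", window_end = "18:00",
                              apply_window = TRUE,
                              solver = solver_config()) {
  if (time_step <= 0) stop("time_step must be > 0 minutes", call. = FALSE)
  if (any(levels < 0 | levels > 1)) {
    stop("illumination levels must lie in [0, 1]", call. = FALSE)
  }
  structure(list(levels = levels, fruit = fruit, scene = scene,
                 reflected_ratio = reflected_ratio, time_step = time_step,
                 window_start = window_start, window_end = window_end,
                 apply_window = apply_window, solver = solver),
            class = "simulation_config")
}

clock_minutes <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(parts[1]) * 60 + as.numeric(parts[2])
}

#' Simulate fruit surface temperature over a weather series
#'
#' Solves the surface energy balance independently at every time step and
#' illumination level (the balance is quasi-steady: no heat storage carries
#' between steps). Rows with a missing required field are dropped with a
#' warning rather than interpolated. Reporting is restricted to the
#' configured daily clock window unless `apply_window = FALSE`.
#'
#' @param weather A weather series data frame with strictly increasing
#'   timestamps.
#' @param config A [simulation_config()].
#' @return A data frame of class `simulation_result` with one row per
#'   (timestamp, level): `timestamp`, `level`, `air_temp`, `fst`,
#'   `fst_minus_air` (degC), the component fluxes `r_abs`, `r_ns`, `r_nl`,
#'   `r_e`, `h`, `le`, `residual` (W m-2), `g_a` (mol m-2 s-1),
#'   `iterations` and `converged`.
#' @export
#' @examples
#' w <- generate_synthetic(synthetic_weather_spec(seed = 42))
#' sim <- run_timeseries(w, simulation_config(levels = c(1, 0)))
#' head(sim)
run_timeseries <- function(weather, config = simulation_config()) {
  validate_weather(weather)
  if (is.null(weather$timestamp) || any(is.na(weather$timestamp))) {
    stop("weather series needs non-missing timestamps", call. = FALSE)
  }
  if (any(diff(as.numeric(weather$timestamp)) <= 0)) {
    stop("weather timestamps must be strictly increasing", call. = FALSE)
  }
  need <- c("air_temp", "rel_humidity", "wind_speed", "shortwave")
  incomplete <- rowSums(is.na(weather[need])) > 0
  if (any(incomplete)) {
    warning(sprintf("dropping %d row(s) with missing weather fields",
                    sum(incomplete)), call. = FALSE)
    weather <- weather[!incomplete, , drop = FALSE]
  }
  if (config$apply_window) {
    mins <- as.numeric(format(weather$timestamp, "%H")) * 60 +
      as.numeric(format(weather$timestamp, "%M"))
    keep <- mins >= clock_minutes(config$window_start) &
      mins <= clock_minutes(config$window_end)
    weather <- weather[keep, , drop = FALSE]
  }
  if (nrow(weather) == 0) stop("no weather rows to simulate", call. = FALSE)

  rows <- vector("list", nrow(weather) * length(config$levels))
  k <- 0
  for (level in config$levels) {
    geom <- illumination_geometry(level, config$reflected_ratio)
    for (i in seq_len(nrow(weather))) {
      w <- weather[i, , drop = FALSE]
      sol <- solve_fst(w, config$fruit, geom, config$scene, config$solver)
      f <- sol$fluxes
      k <- k + 1
      rows[[k]] <- data.frame(
        timestamp = w$timestamp, level = level, air_temp = w$air_temp,
        fst = sol$surface_temp, fst_minus_air = sol$surface_temp - w$air_temp,
        r_abs = f$absorbed, r_ns = f$shortwave_net, r_nl = f$longwave_in,
        r_e = f$emitted, h = f$convective, le = f$latent,
        residual = f$residual, g_a = f$boundary_conductance,
        iterations = sol$iterations, converged = sol$converged
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("simulation_result", "data.frame")
  out
}

#' Heat-flux decomposition of a simulation
#'
#' Tabulates every surface flux with the sign convention that a positive
#' value is a heat gain by the surface: absorbed radiation enters positive,
#' emission, convection and transpiration enter with reversed sign. The four
#' columns therefore sum to the (near-zero) closure residual.
#'
#' @param result A [run_timeseries()] result.
#' @return A data frame with `timestamp`, `level`, `r_abs`, `minus_r_e`,
#'   `minus_h`, `minus_le` and `residual` (all W m-2).
#' @export
flux_decomposition <- function(result) {
  stopifnot(inherits(result, "data.frame"), nrow(result) > 0)
  if (!all(result$converged)) {
    stop("flux decomposition requires a fully converged simulation",
         call. = FALSE)
  }
  data.frame(
    timestamp = result$timestamp, level = result$level,
    r_abs = result$r_abs, minus_r_e = -result$r_e, minus_h = -result$h,
    minus_le = -result$le,
    residual = result$r_abs - result$r_e - result$h - result$le
  )
}

#' Fruit-surface minus air temperature series
#'
#' @param result A [run_timeseries()] result.
#' @return A data frame with `timestamp`, `level` and `fst_minus_air` (degC).
#' @export
fst_air_difference <- function(result) {
  stopifnot(nrow(result) > 0)
  result[c("timestamp", "level", "fst_minus_air")]
}

#' Write a simulation result as delimited text
#'
#' One header row, ISO-8601 timestamps, '.' decimal separator.
#'
#' @param result A [run_timeseries()] result.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(result, path, sep = ",") {
  out <- result[c("timestamp", "level", "air_temp", "fst", "fst_minus_air",
                  "r_abs", "r_e", "h", "le", "residual", "converged")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
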