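#' One-at-a-time perturbation specification
#'
#' Describes which fruit or illumination parameter to perturb and by how
#' much, while every other parameter is held at its reference value.
#' Relative perturbations are multiplicative on the reference (a relative
#' value of `0.05` means +5 percent, `-0.2` means -20 percent, `2` means
#' +200 percent i.e. three times the reference); absolute perturbations
#' replace the reference outright.
#'
#' @param parameter One of `"albedo"`, `"emissivity"`,
#'   `"vapour_conductance"`, `"sunlit_ratio"`.
#' @param values Perturbation values (interpreted per `mode`).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param reference Reference value; `NULL` takes it from the simulation
#'   config at run time.
#' @return A list of class `perturbation_spec`.
#' @export
#' @examples
#' perturbation_spec("emissivity", values = c(-0.05, 0.05))
#' perturbation_spec("vapour_conductance", values = c(0, 1.5e-4),
#'                   mode = "absolute")
perturbation_spec <- function(parameter = c("albedo", "emissivity",
                                            "vapour_conductance",
                                            "sunlit_ratio"),
                              values, mode = c("relative", "absolute"),
                              reference = NULL) {
  structure(list(parameter = match.arg(parameter), values = values,
                 mode = match.arg(mode), reference = reference),
            class = "perturbation_spec")
}

perturbed_value <- function(spec, value, reference) {
  if (spec$mode == "relative") reference * (1 + value) else value
}

apply_perturbation <- function(config, spec, value, level) {
  fruit <- config$fruit
  if (spec$parameter == "sunlit_ratio") {
    ref <- spec$reference %||% level
    level <- perturbed_value(spec, value, ref)
    if (level < 0 || level > 1) {
      stop("perturbed sunlit_ratio outside [0, 1]", call. = FALSE)
    }
  } else {
    ref <- spec$reference %||% fruit[[spec$parameter]]
    new <- perturbed_value(spec, value, ref)
    args <- unclass(fruit)
    args[[spec$parameter]] <- new
    fruit <- do.call(fruit_properties, args)  # revalidates the domain
  }
  config$fruit <- fruit
  config$levels <- level
  config
}

#' One-at-a-time sensitivity analysis of the surface-temperature model
#'
#' Re-solves the whole weather series once per perturbed parameter value and
#' reports the signed surface-temperature change `delta_fst = FST(perturbed)
#' - FST(reference)` (negative = the perturbation cools the fruit). Because
#' it is not obvious which instant of the day a single headline number
#' should describe, the change is reported per time step and summarised two
#' ways: at the sample nearest the midday hour, and at the time the
#' reference temperature peaks.
#'
#' @param weather A weather series data frame.
#' @param config A [simulation_config()]; its first level is the reference
#'   illumination and its fruit holds the reference parameter values
#'   (albedo 0.6, emissivity 0.95, vapour conductance 5e-5 m/s by default).
#' @param spec A [perturbation_spec()].
#' @param midday_hour Clock hour used for the midday summary (default 13).
#' @return A list of class `sensitivity_report`: `per_timestep` (data frame
#'   with `parameter`, `perturbation`, `perturbed_value`, `timestamp`,
#'   `delta_fst`), `summary` (one row per perturbation and summary kind:
#'   `midday` and `daily_max`), and `reference` (the reference simulation).
#' @export
#' @examples
#' w <- generate_synthetic(synthetic_weather_spec(seed = 42))
#' rep <- run_sensitivity(w, simulation_config(),
#'                        perturbation_spec("emissivity", c(-0.05, 0.05)))
#' rep$summary
run_sensitivity <- function(weather, config = simulation_config(), spec,
                            midday_hour = 13) {
  stopifnot(inherits(spec, "perturbation_spec"))
  level <- config$levels[1]
  ref_config <- config
  ref_config$levels <- level
  ref <- run_timeseries(weather, ref_config)

  per <- list()
  summ <- list()
  for (v in spec$values) {
    pert_config <- apply_perturbation(ref_config, spec, v, level)
    sim <- run_timeseries(weather, pert_config)
    delta <- sim$fst - ref$fst
    pv <- if (spec$parameter == "sunlit_ratio") {
      pert_config$levels
    } else {
      pert_config$fruit[[spec$parameter]]
    }
    per[[length(per) + 1]] <- data.frame(
      parameter = spec$parameter, perturbation = v, perturbed_value = pv,
      timestamp = ref$timestamp, delta_fst = delta
    )
    summ[[length(summ) + 1]] <- summarise_delta(ref, delta, spec$parameter,
                                                v, pv, midday_hour)
  }
  structure(list(per_timestep = do.call(rbind, per),
                 summary = do.call(rbind, summ),
                 reference = ref),
            class = "sensitivity_report")
}

summarise_delta <- function(ref, delta, parameter, perturbation,
                            perturbed_value, midday_hour) {
  hrs <- as.numeric(format(ref$timestamp, "%H")) +
    as.numeric(format(ref$timestamp, "%M")) / 60
  i_mid <- which.min(abs(hrs - midday_hour))
  i_max <- which.max(ref$fst)
  data.frame(
    parameter = parameter, perturbation = perturbation,
    perturbed_value = perturbed_value,
    summary_kind = c("midday", "daily_max"),
    delta_fst = c(delta[i_mid], delta[i_max])
  )
}

#' Surface-temperature response to the illumination level
#'
#' Runs the series at each illumination level A_d/A and reports the change
#' relative to the fully sunlit run (level 1), which is the hottest and
#' serves as the reference: every other level comes out at or below it.
#' Unless pinned through the config, the reflected-radiation ratio follows
#' the level-dependent default mapping.
#'
#' @param weather A weather series data frame.
#' @param config A [simulation_config()].
#' @param levels Illumination levels to compare (the reference level 1 is
#'   added if absent).
#' @param midday_hour Clock hour used for the midday summary (default 13).
#' @return A `sensitivity_report` whose `per_timestep` and `summary` carry
#'   one entry per level with `delta_fst` relative to level 1.
#' @export
illumination_grid <- function(weather, config = simulation_config(),
                              levels = c(1, 0.8, 0.6, 0.5, 0.4, 0.2, 0),
                              midday_hour = 13) {
  if (any(levels < 0 | levels > 1)) {
    stop("illumination levels must lie in [0, 1]", call. = FALSE)
  }
  levels <- sort(unique(c(1, levels)), decreasing = TRUE)
  ref_config <- config
  ref_config$levels <- 1
  ref <- run_timeseries(weather, ref_config)
  per <- list()
  summ <- list()
  for (lv in levels) {
    cfg <- config
    cfg$levels <- lv
    sim <- if (lv == 1) ref else run_timeseries(weather, cfg)
    delta <- sim$fst - ref$fst
    per[[length(per) + 1]] <- data.frame(
      parameter = "sunlit_ratio", perturbation = lv - 1, perturbed_value = lv,
      timestamp = ref$timestamp, delta_fst = delta
    )
    summ[[length(summ) + 1]] <- summarise_delta(ref, delta, "sunlit_ratio",
                                                lv - 1, lv, midday_hour)
  }
  structure(list(per_timestep = do.call(rbind, per),
                 summary = do.call(rbind, summ),
                 reference = ref),
            class = "sensitivity_report")
}

#' Write a sensitivity summary as delimited text
#'
#' @param report A `sensitivity_report`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(report, path, sep = ",") {
  utils::write.table(report$summary, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
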