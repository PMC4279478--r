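#' Validation statistics for simulated against measured surface temperature
#'
#' Joins a simulated and a measured surface-temperature series on nearest
#' timestamp within a tolerance and computes the usual agreement
#' statistics. Errors are defined as simulated minus measured. Because it is
#' ambiguous which series should be the regressor, both regression slopes
#' are reported: `slope`/`intercept` regress simulated on measured,
#' `slope_rev`/`intercept_rev` the reverse. Both the mean and the maximum
#' absolute error are included.
#'
#' @param sim_series Data frame with `timestamp` and a temperature column
#'   (`fst` or `value`); a [run_timeseries()] result works directly (restrict
#'   it to one illumination level first).
#' @param measured_series Data frame with `timestamp` and a temperature
#'   column (`fst`, `value` or `measured`).
#' @param join_tolerance Maximum timestamp mismatch for a pair, minutes
#'   (default 5; imaging and station clocks rarely agree exactly).
#' @return An object of class `validation_report`: list with `n`, `rmse`,
#'   `r_squared`, `slope`, `intercept`, `slope_rev`, `intercept_rev`,
#'   `error_mean`, `error_sd`, `mae`, `max_abs_error` (temperatures in degC).
#' @export
#' @examples
#' w <- generate_synthetic(synthetic_weather_spec(seed = 42))
#' sim <- run_timeseries(w, simulation_config(levels = 1))
#' validate(sim, data.frame(timestamp = sim$timestamp, value = sim$fst))
validate <- function(sim_series, measured_series, join_tolerance = 5) {
  pick <- function(df, candidates) {
    nm <- intersect(candidates, names(df))
    if (!length(nm)) {
      stop("series needs one of the columns: ",
           paste(candidates, collapse = ", "), call. = FALSE)
    }
    df[[nm[1]]]
  }
  ts_sim <- as.numeric(sim_series$timestamp)
  ts_meas <- as.numeric(measured_series$timestamp)
  v_sim <- pick(sim_series, c("fst", "value", "temperature"))
  v_meas <- pick(measured_series, c("measured", "fst", "value", "temperature"))

  tol <- join_tolerance * 60
  idx <- vapply(ts_meas, function(t) {
    j <- which.min(abs(ts_sim - t))
    if (abs(ts_sim[j] - t) <= tol) j else NA_integer_
  }, integer(1))
  ok <- !is.na(idx)
  sim <- v_sim[idx[ok]]
  meas <- v_meas[ok]
  n <- length(sim)
  if (n < 2) {
    stop(sprintf("only %d joinable pair(s) within %g min; need at least 2",
                 n, join_tolerance), call. = FALSE)
  }
  err <- sim - meas
  fit <- stats::lm(sim ~ meas)
  fit_rev <- stats::lm(meas ~ sim)
  r2 <- if (stats::var(meas) > 0 && stats::var(sim) > 0) {
    stats::cor(sim, meas)^2
  } else if (all(err == err[1])) 1 else 0  # degenerate constant series
  structure(list(
    n = n,
    rmse = sqrt(mean(err^2)),
    r_squared = r2,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_rev = unname(stats::coef(fit_rev)[2]),
    intercept_rev = unname(stats::coef(fit_rev)[1]),
    error_mean = mean(err),
    error_sd = stats::sd(err),
    mae = mean(abs(err)),
    max_abs_error = max(abs(err))
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation on %d pairs\n", x$n))
  cat(sprintf("  RMSE %.3f degC | R^2 %.3f | MAE %.3f | max |err| %.3f\n",
              x$rmse, x$r_squared, x$mae, x$max_abs_error))
  cat(sprintf("  sim ~ meas: slope %.3f, intercept %.3f\n",
              x$slope, x$intercept))
  cat(sprintf("  meas ~ sim: slope %.3f, intercept %.3f\n",
              x$slope_rev, x$intercept_rev))
  cat(sprintf("  error mean %.3f, sd %.3f degC\n", x$error_mean, x$error_sd))
  invisible(x)
}

#' Write a validation report as flat key=value text
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation <- function(report, path) {
  keys <- names(unclass(report))
  lines <- vapply(keys, function(k) {
    sprintf("%s=%.6g", k, report[[k]])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
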