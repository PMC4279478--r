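#' Solver settings for the surface-temperature root find
#'
#' @param bracket_below,bracket_above Width of the search bracket below and
#'   above air temperature, degC (defaults 20 and 40).
#' @param tol Root tolerance on temperature, degC (default 1e-4).
#' @param maxiter Maximum iterations (default 200).
#' @param closure_tol Flux-closure tolerance for declaring convergence,
#'   W m-2 (default 0.01).
#' @param slope_at Linearization point for the saturation-curve slope, see
#'   [psychrometric_state()].
#' @return A list of solver settings.
#' @export
solver_config <- function(bracket_below = 20, bracket_above = 40,
                          tol = 1e-4, maxiter = 200, closure_tol = 0.01,
                          slope_at = c("air", "dewpoint")) {
  list(bracket_below = bracket_below, bracket_above = bracket_above,
       tol = tol, maxiter = maxiter, closure_tol = closure_tol,
       slope_at = match.arg(slope_at))
}

#' Solve the surface energy balance for the fruit surface temperature
#'
#' Finds the surface temperature at which absorbed radiation balances
#' emission, convection and transpiration. The balance reduces to a quartic
#' in the absolute surface temperature; rather than extracting quartic roots
#' the solver brackets the (strictly decreasing) residual over
#' `[T_a - 20, T_a + 40]` degC and bisects with [stats::uniroot()], which is
#' guaranteed to converge to the unique physical root.
#'
#' @param weather A single weather record ([weather_sample()] or a one-row
#'   data frame with its columns).
#' @param fruit [fruit_properties()].
#' @param geom [illumination_geometry()].
#' @param scene [scene_properties()].
#' @param config [solver_config()].
#' @return An object of class `fst_solution`: list with `surface_temp`
#'   (degC), `fluxes` (the [energy_residual()] terms at the solution),
#'   `iterations` and `converged` (`TRUE` iff the absolute residual is below
#'   the closure tolerance).
#' @export
#' @examples
#' w <- weather_sample(air_temp = 32, rel_humidity = 30, wind_speed = 3.5,
#'                     shortwave = 900)
#' sol <- solve_fst(w, fruit_properties(), illumination_geometry(1),
#'                  scene_properties())
#' sol$surface_temp
solve_fst <- function(weather, fruit = fruit_properties(),
                      geom = illumination_geometry(),
                      scene = scene_properties(),
                      config = solver_config()) {
  validate_weather(weather)
  psychro <- psychrometric_state(weather, slope_at = config$slope_at)
  f <- function(t) {
    energy_residual(t, weather, psychro, fruit, geom, scene)$residual
  }
  lo <- weather$air_temp - config$bracket_below
  hi <- weather$air_temp + config$bracket_above
  f_lo <- f(lo)
  f_hi <- f(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(paste0("energy balance has no root in [%.1f, %.1f] degC: ",
                        "residual %.1f W/m2 at the lower and %.1f W/m2 at ",
                        "the upper endpoint"), lo, hi, f_lo, f_hi),
         call. = FALSE)
  }
  root <- stats::uniroot(f, lower = lo, upper = hi, f.lower = f_lo,
                         f.upper = f_hi, tol = config$tol,
                         maxiter = config$maxiter)
  fluxes <- energy_residual(root$root, weather, psychro, fruit, geom, scene)
  structure(list(
    surface_temp = root$root,
    fluxes = fluxes,
    iterations = root$iter,
    converged = abs(fluxes$residual) < config$closure_tol
  ), class = "fst_solution")
}

#' @export
print.fst_solution <- function(x, ...) {
  cat(sprintf("Fruit surface temperature: %.3f degC (%s, %d iterations)\n",
              x$surface_temp,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  f <- x$fluxes
  cat(sprintf("  R_abs %.1f = R_e %.1f + H %.1f + lE %.1f  (residual %.2e W/m2)\n",
              f$absorbed, f$emitted, f$convective, f$latent, f$residual))
  invisible(x)
}
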