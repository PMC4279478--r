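#' Physical constants used by the energy-balance model
#'
#' Returns the fixed physical and empirical constants of the model. These are
#' the values a biophysical energy-budget treatment of a sphere in cross-flow
#' uses and are not meant to be tuned.
#'
#' @return A named list:
#' \describe{
#'   \item{stefan_boltzmann}{Stefan-Boltzmann constant, 5.67e-8 W m-2 K-4.}
#'   \item{cp_air_molar}{Molar heat capacity of air, 29.3 J mol-1 degC-1.}
#'   \item{latent_heat_vap}{Latent heat of vaporisation of water, 2.429e6 J/kg.}
#'   \item{outdoor_factor}{Empirical outdoor enhancement of the boundary-layer
#'     conductance, 1.4 (turbulence in the open relative to laminar theory).}
#'   \item{conductance_coeff}{Forced-convection conductance coefficient,
#'     0.135 mol m-2 s-1 per sqrt(m s-1 / m).}
#'   \item{shape_factor}{Characteristic-length factor for a sphere, 0.84
#'     (multiplies the fruit diameter).}
#'   \item{r_dry_air}{Specific gas constant of dry air, 287.04 J kg-1 K-1.}
#'   \item{kelvin_offset_rad}{Celsius-to-Kelvin offset used in the radiative
#'     T^4 terms (273, kept as the model's original convention).}
#'   \item{kelvin_offset}{Celsius-to-Kelvin offset used in psychrometric and
#'     emissivity helpers (273.15).}
#' }
#' @export
#' @examples
#' physical_constants()$stefan_boltzmann
physical_constants <- function() {
  list(
    stefan_boltzmann  = 5.67e-8,
    cp_air_molar      = 29.3,
    latent_heat_vap   = 2.429e6,
    outdoor_factor    = 1.4,
    conductance_coeff = 0.135,
    shape_factor      = 0.84,
    r_dry_air         = 287.04,
    kelvin_offset_rad = 273,
    kelvin_offset     = 273.15
  )
}

# internal shortcut; constants are immutable so a single list is shared
.const <- list(
  stefan_boltzmann  = 5.67e-8,
  cp_air_molar      = 29.3,
  latent_heat_vap   = 2.429e6,
  outdoor_factor    = 1.4,
  conductance_coeff = 0.135,
  shape_factor      = 0.84,
  r_dry_air         = 287.04,
  kelvin_offset_rad = 273,
  kelvin_offset     = 273.15
)

`%||%` <- function(x, y) if (is.null(x)) y else x
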