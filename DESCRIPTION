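Package: fruitheat
Title: Fruit Surface Temperature from a Surface Energy Balance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the maximum surface temperature of sun-exposed fruit
    (apple) from standard weather-station data (air temperature, relative
    humidity, wind speed, incoming short-wave radiation) by solving a
    quasi-steady surface energy balance: absorbed short- and long-wave
    radiation against grey-body emission, forced-convective sensible heat
    and a linearized transpirational latent-heat flux. Includes a 15-minute
    time-series driver, one-at-a-time parameter sensitivity analyses, an
    illumination-ratio grid, flux decomposition, a seeded synthetic
    clear-sky weather generator, weather file input/output with resampling,
    and validation statistics against measured surface-temperature series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
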