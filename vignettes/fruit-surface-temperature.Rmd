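---
title: "Modelling the maximum fruit surface temperature from weather data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the maximum fruit surface temperature from weather data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitheat)
```

## The problem

Sun-exposed apples routinely run 10 °C or more above air temperature on
clear summer afternoons — hot enough to scald the skin (sunburn), a major
cause of culled fruit. Orchardists who schedule evaporative cooling from air
temperature alone systematically under-estimate the risk. `fruitheat`
predicts the temperature of the hottest point on the fruit surface from the
variables any agricultural weather station records: air temperature,
relative humidity, wind speed and incoming short-wave radiation.

## The model

The hottest surface point is treated as quasi-steady at each 15-minute time
step: the heat absorbed must equal the heat shed,

$$R_{abs} = R_e + H + \lambda E .$$

Heat storage, within-fruit conduction, plant-to-fruit water flux and
metabolic heat are all neglected — at a single skin point over 15 minutes
they are small against the radiative and convective terms.

**Absorbed radiation.** Short-wave input scales with the sunlit-area ratio
$A_d/A$ (1 = fully sunlit, 0 = fully shaded) and the skin reflectance
(albedo) $\alpha \approx 0.6$:
$R_{ns} = (A_d/A)\,(1-\alpha)\,R_s$. Long-wave input sums clear-sky
atmospheric emission and ground/canopy emission intercepted over the
empirical reflected-area ratio $A_r/A'$ (at most 0.6):
$R_{nl} = \varepsilon_a \sigma (T_a+273)^4 +
 (A_r/A')\,\varepsilon_g \sigma (T_{gmean}+273)^4$.

**Emission.** Grey-body: $R_e = \varepsilon_f \sigma (T_{fs}+273)^4$ with
$\varepsilon_f = 0.95$ for apple skin.

**Convection.** Forced only: $H = c_p\,g_a\,(T_{fs}-T_a)$ with molar
$c_p = 29.3$ J mol⁻¹ °C⁻¹ and a sphere-in-crossflow boundary-layer
conductance $g_a = 1.4 \times 0.135 \sqrt{u/d}$, where $d = 0.84 \times$
fruit diameter and the 1.4 is the empirical outdoor-turbulence enhancement.
Still air gives $g_a = 0$: free convection is not modelled, so predictions
in near-calm conditions are a lower bound on ventilation.

**Transpiration.** The vapour flux through the skin (conductance
$g_w \approx 5\times10^{-5}$ m/s) is linearized about air temperature:
$\lambda E = \lambda g_w \rho_{air} [\Delta (T_{fs}-T_a) + (e_s(T_a)-e_a)]/P$,
with $\lambda = 2.429$ MJ/kg and $\Delta$ the slope of the saturation
vapour-pressure curve.

Substituting everything into the balance gives a quartic in
$T_{fs} + 273$. Rather than extract quartic roots and pick the physical
one, `solve_fst()` exploits that every loss term is increasing in $T_{fs}$,
so the residual $R_{abs} - R_e - H - \lambda E$ is strictly decreasing and
has exactly one root. Bracketed root finding over
$[T_a - 20, T_a + 40]$ °C (via `uniroot`, tolerance $10^{-4}$ °C, at most
200 iterations) is guaranteed to converge to it; a solution is flagged
converged only if the flux closure $|R_{abs}-R_e-H-\lambda E|$ is below
0.01 W m⁻².

## Supporting formulas

The psychrometric and sky-emissivity relations are the standard
agrometeorological forms:

* Tetens saturation vapour pressure
  $e_s(T) = 0.611\,\exp[17.502\,T/(T+240.97)]$ kPa, with $\Delta$ its
  analytic derivative. By default $\Delta$ is evaluated at $T_a$ — the
  point about which the latent flux is expanded — with a switch
  (`solver_config(slope_at = "dewpoint")`) for the dew-point convention.
* Dry-air density from the ideal gas law,
  $\rho_{air} = 1000 P / (287.04\,T_K)$.
* Clear-sky atmospheric emissivity: Brutsaert
  $\varepsilon_a = 1.24 (e_a[\mathrm{hPa}]/T_K)^{1/7}$ by default, with a
  quadratic clear-sky form $9.2\times10^{-6} T_K^2$ and a fixed value as
  alternatives.

Radiative $T^4$ terms use the +273 Kelvin offset (the model's original
convention); the helpers above use 273.15. The split is deliberate and
changes results by well under the solver tolerance's practical relevance.

## Parameters that matter

| Parameter | Default | Units | Effect at a hot clear midday |
|---|---|---|---|
| albedo $\alpha$ | 0.6 | – | ±20 % moves the surface ≈ 2 °C |
| emissivity $\varepsilon_f$ | 0.95 | – | +5 % cools ≈ 0.6–0.8 °C |
| skin conductance $g_w$ | 5e-5 | m/s | 0 to 3× moves ≤ 0.5 °C |
| sunlit ratio $A_d/A$ | 1 | – | full shade is ≈ 7 °C cooler |
| reflected ratio $A_r/A'$ | 0.6 | – | level-paired default below |
| diameter | 0.075 | m | enters through $g_a \propto d^{-1/2}$ |
| ground emissivity $\varepsilon_g$ | 0.95 | – | long-wave floor |

The $A_r/A'$ default follows the empirical pairing with illumination:
0.6 for fully sunlit and fully shaded fruit, 0.3 for half-sunlit fruit
(`default_reflected_ratio()`), always overridable. Note that this pairing
makes fruit temperature non-monotone across illumination levels near 0.5 —
half-sunlit fruit sees less reflected long-wave. The illumination grid is
therefore only strictly monotone in $A_d/A$ when $A_r/A'$ is pinned, which
is how the package's ordering tests run it.

## Sensitivity analyses

`run_sensitivity()` perturbs one parameter at a time while the others stay
at their reference values (α = 0.6, ε_f = 0.95, g_w = 5e-5 m/s) and
re-solves the whole series; `illumination_grid()` does the same across
$A_d/A$ levels against the fully sunlit run. Percent perturbations are
multiplicative on the reference (±5 % of 0.95 → 0.9025/0.9975; "+200 %" →
3×; ±20 % of 0.6 → 0.48/0.72 — interpreted as relative, not ±0.2
absolute). Because a single headline ΔFST could describe different instants
of the day, the report gives the change per time step plus two summaries:
at the sample nearest a configurable midday hour (default 13:00) and at the
time the reference temperature peaks. Signs follow the physics: raising
$\varepsilon_f$ or $g_w$ cools, lowering $\alpha$ or raising $A_d/A$ warms.

## Synthetic weather

`generate_synthetic()` produces the forcing every other module is tested
with: a clear-sky half-sine of solar radiation between fixed 06:00 and
20:00 (the model consumes measured radiation, so astronomical sunrise
geometry would add nothing to the tests), an air-temperature sinusoid
between the daily extremes peaking at 14:00, relative humidity linearly
anticorrelated with temperature, and wind as a seeded truncated Gaussian.
Defaults describe a hot dry mid-August day (peak 900 W m⁻², 18–32 °C,
25–70 % RH, 2.5 ± 0.5 m/s wind). Timestamps label the start of each
half-open 15-minute window.

What the generator does *not* emulate — clouds, canopy shading transients,
wind gust spectra, humidity fronts — bounds what passing tests show: they
demonstrate the solver and its couplings are correct under smooth clear-sky
forcing, not that field accuracy matches any particular orchard record.
Validation against measured fruit temperatures is what `validate()` is for
(RMSE, R², both regression directions, error mean/SD, mean and maximum
absolute error, nearest-timestamp join with a 5-minute default tolerance).

## Numerical choices and degenerate inputs

* Residual monotonicity makes the bracketed root unique; if the bracket
  does not change sign (pathological forcing, e.g. multi-kW absorbed
  radiation with near-zero ventilation) the solver raises an error
  reporting both endpoint residuals rather than returning an extrapolation.
* Zero wind gives zero boundary-layer conductance; the balance then closes
  through radiation and transpiration alone.
* Weather rows with missing required fields are dropped with a warning,
  never interpolated — silently fabricating forcing is worse than a gap.
* The 11:00–18:00 daily reporting window (when sunburn develops) filters
  output, not solving, and can be disabled.
* Each time step is solved independently; no state carries between steps.

## Worked example

```{r example, eval = FALSE}
w <- generate_synthetic(synthetic_weather_spec(seed = 42))
sim <- run_timeseries(w, simulation_config(levels = c(1, 0.5, 0)))
aggregate(fst_minus_air ~ level, fst_air_difference(sim), max)

rep <- run_sensitivity(w, simulation_config(),
                       perturbation_spec("emissivity", c(-0.05, 0.05)))
rep$summary
```

The test suite exercises the solver against an exhaustive grid-search
oracle on 100 randomized weather draws (0.001 °C spacing), checks flux
closure on 1000 randomized solves, and reproduces the canonical-midday
sensitivity magnitudes (problem sizes chosen to keep the whole suite in the
tens of seconds).

## Known limitations

Clear-sky days only; forced convection only; no canopy radiative transfer
or within-canopy wind attenuation; quasi-steady (no sub-15-min thermal
inertia); the hottest-point abstraction says nothing about the temperature
field over the rest of the fruit.
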