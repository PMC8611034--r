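# coolcity

How much cooler are urban trees — and treeless urban green spaces — than
dense urban fabric, and how does that cooling behave during the hottest
conditions a city experiences? `coolcity` answers this from satellite land
surface temperature (LST) scenes, for analysts studying surface urban heat
islands and heat-mitigation potential, and validates every stage of the
chain by parameter recovery on synthetic cities with fully known truth.

## The method

For each LST scene a penalized additive model is fitted over the analysis
grid (cells of 30–90 m):

    T(s) = β₀ + g(x, y) + h₁(elev) + h₂(north) + Σₖ sₖ(fₖ) + ε

with a tensor-product smooth `g` over coordinates absorbing smooth spatial
confounding, thin-plate splines for elevation and north-facing slope
fraction, and one smooth per land-use/land-cover (LULC) cover fraction `fₖ`
(urban trees are an independent overlay). The cooling contrast is the
difference between two counterfactual predictions at identical reference
covariates — 100% cover of class *a* versus 100% continuous urban fabric:

    ΔT = [s_a(1) − s_a(0)] − [s_fabric(1) − s_fabric(0)]

a linear functional of the spline coefficients, with a delta-method
standard error. Per-scene contrasts are then regressed on background air
temperature T_b with robust local linear regression (tricube weights,
Tukey-bisquare re-descending reweighting at 6·median|r|); the curve's value
at the maximum observed T_b is the **hot-extreme cooling**. City results are
synthesized regionally (2-D smooth trend surfaces, group means ± se), and
per-class evapotranspiration/albedo signatures are attributed by linear
unmixing of coarse rasters on sub-pixel class fractions (no intercept, so
coefficients are per-class values; negative ET estimates are flagged and
excluded from associations).

Fitting uses `mgcv`; the contrast machinery, robust loess, unmixing and the
synthetic-city generator are implemented here. See `vignettes/methods.Rmd`
for assumptions, tuning parameters and limitations.

## Worked example

Generate a synthetic city with planted tree cooling −4 − 0.2·(T_b − 10) K
against fabric, fit every scene, and recover the cooling curve:

```r
library(coolcity)

truth <- truth_config(seed = 101)                 # reference planting
city  <- synth_city(truth, nrow = 300, ncol = 300,
                    analysis_cell_size = 90, n_scenes = 60)
rec   <- recover_city(city)                       # fits 60 additive models

mean(rec$contrasts$covered)                       # planted value in ±2 se
#> [1] 0.9333333
str(rec$endpoint)                                 # hot-extreme cooling
#> List of 3
#>  $ tb     : num 28.6
#>  $ delta_t: num -7.75
#>  $ se     : num 0.0203
rec$planted_endpoint                              # generator truth at max Tb
#> [1] -7.72281
subset(rec$seasonal, season == "JJA")[c("n", "q1", "median", "q3")]
#>    n        q1    median        q3
#> 3 16 -6.856836 -6.615984 -6.201428
```

93% of the 60 per-scene contrasts cover the planted truth within two
standard errors; the hot-extreme endpoint (−7.75 ± 0.02 K at
T_b = 28.6 °C) sits 0.03 K from the planted value; summer cooling
(JJA median −6.6 K) is weaker than the hot extreme, as planted for this
energy-limited configuration.

The numbered drivers under `analysis/` run the full workflow and write
tables under `results/`: `01_build_city.R` (generate + export the reference
city), `02_scene_contrasts.R` (per-scene contrasts vs truth),
`03_cooling_curves.R` (curves, endpoints, seasonal summaries, hot-extreme
regimes), `04_unmixing.R` (ET/albedo signatures), `05_regional.R` (20-city
transect: trend surface, regional means, ET association),
`06_calibration.R` (endpoint interval coverage).

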