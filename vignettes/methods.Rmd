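---
title: "Counterfactual land-cover contrasts of urban land surface temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual land-cover contrasts of urban land surface temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the estimand

Cities are mosaics of land-use/land-cover (LULC) classes — continuous urban
fabric, treeless green spaces, patches and rows of urban trees — and satellite
land surface temperature (LST) scenes observe the mosaic, not the pure
classes. The quantity of interest is nevertheless a pure-class contrast: how
much cooler would a grid cell be if it were 100% covered by urban trees
rather than 100% continuous urban fabric, under the conditions of one
particular scene? `coolcity` estimates this counterfactual contrast per
scene, traces how it varies with background air temperature, extracts its
value under the hottest conditions on record, and relates its between-city
variation to per-class evapotranspiration (ET) and albedo obtained by
unmixing coarse satellite products.

Negative contrasts mean vegetation is cooler than fabric; we call that
cooling.

## The per-scene additive model

For one LST scene, each analysis cell (30 or 90 m) carries the response
$T(s)$ and covariates: projected coordinates $(x, y)$, elevation, the
fraction of north-facing slopes, and the cover fraction $f_k$ of each
modelled LULC class (urban trees are an overlay mapped independently of the
mutually exclusive classes). The model is additive and penalized:

$$
T(s) = \beta_0 + g(x, y) + h_1(\mathrm{elev}) + h_2(\mathrm{north})
  + \sum_k s_k(f_k) + \varepsilon,
$$

with $g$ a tensor-product smooth (default basis $5 \times 5$) absorbing
smooth spatial confounding, and $h_j$, $s_k$ thin-plate regression splines
(default basis 5). Smoothing parameters are selected by REML (GCV is a
configuration option), via `mgcv`. There is deliberately no
space-by-land-cover interaction: the target is the city-average effect of a
class, not its local pattern.

The contrast between classes $a$ and $b$ is the difference of two model
predictions sharing the same reference covariates (city means), one with
$f_a = 1$ and all other modelled fractions 0, one with $f_b = 1$:

$$
\Delta T_{a\mathrm{-}b} = [s_a(1) - s_a(0)] - [s_b(1) - s_b(0)].
$$

This is a linear functional $d^\top\beta$ of the spline coefficients, so its
standard error follows from the coefficient covariance by the delta method,
$\mathrm{se} = \sqrt{d^\top V d}$. Under additivity the contrast is invariant
to constant shifts of the response or of any other covariate — a property
the tests exercise directly.

Two modelling rules matter in practice:

* **Predictor list.** Every class of the vocabulary enters the model except
  one "complement" class that is named in no contrast; fractions sum to one,
  so modelling all of them would alias the intercept. Crucially, classes
  with a thermal signal of their own must *not* be omitted: leaving, say,
  green spaces out of the model while contrasting trees against fabric
  biases the tree term by whatever green-space signal is spatially
  correlated with it. Parameter-recovery experiments during development
  showed per-scene interval coverage dropping from ~93% to ~70% when
  signal-bearing classes were omitted.
* **Extrapolation.** The prediction at $f = 1$ is computed even when no
  cell reaches fraction 1; the contrast is then flagged
  (`extrapolation_flag`) whenever the maximum observed fraction of either
  class falls below 0.9. The flag is transparency, not a filter.

Scenes are rejected (and recorded as failures, never dropped silently) when
fewer usable cells remain than ten times the total basis dimension, or when
the response is constant; constant covariates are dropped from the formula
with a warning.

## The cooling curve and the hot extreme

Each scene yields one $\Delta T$ with a date and a background temperature
$T_b$ — from a date-keyed gridded air-temperature table when available,
otherwise the scene's spatial mean LST. The relation $\Delta T(T_b)$ is
fitted by robust local linear regression:

* tricube distance weights with a nearest-neighbour bandwidth: the window at
  $x_0$ spans the $q = \lfloor \mathrm{span} \cdot n \rfloor$ nearest
  points (span defaults to 0.75);
* `robust_iters` (default 4) reweighting passes with Tukey-bisquare weights
  on residuals scaled by $6\,\mathrm{median}|r|$ — a re-descending
  M-estimator whose influence vanishes for gross outliers;
* evaluation strictly inside the observed $T_b$ range; the **hot-extreme
  cooling** is the curve value at the maximum observed $T_b$, with the
  pointwise standard error of the local fit at that boundary.

With zero robust iterations the procedure reduces exactly to plain tricube
loess; the test suite pins this equivalence to `stats::lowess(iter = 0,
delta = 0)` at $10^{-10}$. Two numerical choices are documented because they
affect inference:

* the bisquare-weighted residual variance underestimates $\sigma^2$ under
  clean Gaussian scatter; it is divided by its Gaussian consistency constant
  $E[w z^2]/E[w] = 0.77558$ (bisquare at $k = 6 \times 0.67449\,\sigma$);
* when the robust fit becomes exact on a clean majority the residual scale
  collapses to zero; the iteration then freezes, keeping the exactly fitted
  points and discounting the rest entirely, instead of resetting weights.

Seasonal summaries use calendar-month seasons (DJF/MAM/JJA/SON) and type-7
quartiles; empty seasons are reported with a count of zero.

**Resolving the hot tail.** The endpoint is only as good as the hottest few
scenes. If the cooling-temperature relation bends within a few K of the
maximum (the soil-moisture-limited regime), a wide span cannot see the bend:
the one-sided endpoint window reaches far back into the pre-break regime,
and — worse — the bisquare pass then discounts the genuinely hot scenes as
apparent outliers. The regime study therefore uses dense scene sets (400
scenes, the order long satellite records actually provide per city) and a
span of 0.1, so the endpoint bandwidth covers only the top few K. This is a
bias-variance choice: per-scene contrast errors here are ~0.05 K, so narrow
windows cost little variance.

## Regional synthesis and attribution

Per-city results (hot-extreme endpoint, JJA median, per-pair) are smoothed
over projected city coordinates with a penalized 2-D thin-plate spline —
an interpolation of city values revealing continental gradients — and
summarised per region/country by mean, $\mathrm{sd}/\sqrt{n}$ and count
(singleton groups report a missing se). The association between cooling and
a driver (e.g. forest ET) is an ordinary least-squares line with its $R^2$.
Coordinates are taken as given in a projected metric system; no geodesy is
implemented.

## Unmixing coarse ET and albedo

Coarse pixels (hundreds of metres to a km) mix the per-class signatures
linearly. Regressing pixel values on sub-pixel class fractions **without an
intercept** makes each coefficient directly the per-class value; an
intercept-plus-baseline parameterization would give identical predictions,
but the no-intercept form is the simpler contract. Blue-sky albedo is
approximated as the mean of white- and black-sky albedo; monthly
climatologies are cellwise multi-year means ignoring missing cells. Rank
deficiency (a class absent from all unmasked pixels) drops the aliased class
with a warning; cities with fewer than $3 \times$ the class count of
unmasked pixels are rejected; negative ET signatures are physically
impossible and are flagged — excluded from downstream association analyses
but never clamped, preserving the audit trail.

Because satellite ET is generally unavailable over built-up areas, the
synthetic ET product masks pixels whose summed urban-class fraction exceeds
0.5; vegetation signatures are therefore estimated from peri-urban pixels,
as they must be with the real products.

## The synthetic-city generator

Every stage is validated by parameter recovery on synthetic cities with
fully known truth:

* **Land cover**: nearest-seed (Voronoi) tessellation with per-class seed
  counts proportional to target shares — contiguous patches with mixed
  fractions at analysis-cell borders. Default shares: fabric 0.40, trees
  0.22, green spaces 0.20, other impervious 0.18.
* **Terrain and confounder**: DEM and the spatial trend are seeded sums of a
  few sinusoids, band-limited below ~0.8 cycles per domain so that the
  default $5 \times 5$ tensor smooth can absorb them — the structural
  assumption of the analysis, built into the generator on purpose.
* **Scenes**: $T(s) = T_b + \sum_k f_k\,\mathrm{offset}_k(T_b) +
  \mathrm{lapse}\,(\mathrm{elev} - \overline{\mathrm{elev}}) +
  \mathrm{trend}(x, y) + \varepsilon$, with independent Bernoulli cell
  masking standing in for clouds. Offsets are functions of $T_b$; the
  baseline class (continuous urban fabric) has the zero offset, so the
  planted contrast of any class against fabric is its own offset function.
  Reference planting: trees $-4 - 0.2\,(T_b - 10)$ K, green spaces
  $-1.5 - 0.075\,(T_b - 10)$ K (one third of the tree cooling), other
  impervious $-0.5$ K.
* **Conditions**: dates uniform over 2006–2018; $T_b$ follows a sinusoidal
  seasonal cycle (mean 13 °C, half-amplitude 11 °C, scatter 2.5 °C), so
  JJA and hot-extreme logic is exercised; scene noise 0.5 K, confounder
  amplitude 2 K, 10% masking in the reference configuration.
* **Coarse products**: exact fraction mixtures of per-class ET/albedo
  signatures (+ optional noise); white/black-sky albedo are the blue-sky
  mixture ± a fixed diffuse-direct split, so their average recovers the
  planted blue-sky value exactly.

What the generator does **not** emulate: realistic urban morphology,
anisotropy and shadowing, radiative transfer, spatially coherent cloud
geometry, autocorrelated noise. Passing recovery tests therefore demonstrate
the statistical machinery under the model's own assumptions — additivity,
smooth confounding, independent noise — not robustness to violations of
them.

## Problem sizes and study design

The reference recovery study uses one 300 × 300-cell city at 10 m with a
90 m analysis grid (~1100 analysis cells) and 60 scenes; per-scene fits use
REML via `gam`. The calibration study replicates the reference city's
observational process 100 times at 40 scenes per replicate, holding the
geography fixed and redrawing dates, temperatures, noise and masks — the
replication unit is the observational process, not the city — and uses the
fast-REML `bam` engine with discretised covariates for the ~4000 scene
fits. Endpoint intervals use the t quantile at the residual degrees of
freedom of the final local fit. Measured coverage of the planted endpoint is
92% (nominal band 90–99%).

The multi-city demonstration (`analysis/05_regional.R`) uses twenty
150 × 150 cities on an east–west transect with a planted cooling ramp and a
planted linear ET–cooling relation across cities, recovering the ramp slope
and the association within 10%.

## Known limitations

* Delta-method standard errors are conditional on the selected smoothing
  parameters; under strong unabsorbed confounding they are optimistic.
* The spatial smooth absorbs confounders only up to its basis resolution;
  confounding at finer scales biases the class terms (the generator's
  band limit makes this explicit).
* The endpoint inherits the noise of the hottest few scenes; with sparse
  hot tails the robust pass can discount genuine hot-extreme behaviour
  (see "Resolving the hot tail").
* Counterfactual predictions at fraction 1 are extrapolations wherever no
  pure cell is observed; they are flagged, not corrected.
* Real-data mode reads plain-text rasters (ESRI ASCII grids) and a scene
  metadata table; reprojection, atmospheric correction and LST retrieval
  are upstream of this package.
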