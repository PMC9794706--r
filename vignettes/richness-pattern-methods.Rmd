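---
title: "Methods: elevational and spatial richness patterns with richscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elevational and spatial richness patterns with richscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richscape)
```

`richscape` analyses the species-richness pattern of threatened plants along
an elevational gradient and across a 20-km spatial grid, and attributes that
pattern to climatic, topographic and anthropogenic drivers. This vignette
documents the models and procedures, the tunable parameters and their
defaults, the synthetic-landscape generator used for validation, and the
numerical choices made where conventions were genuinely open.

## Elevational richness by range interpolation

The elevational domain is cut into bands of width 100 m, each identified by
its elevation mark, inclusive at both ends: a 200–4800 m domain yields
$(4800-200)/100 + 1 = 47$ bands. Under range interpolation a species with
recorded limits $[l, u]$ is assumed present in every band between $l$ and
$u$; a species ranging 1300–1700 m occupies exactly the bands 1300, 1400,
1500, 1600 and 1700. Interpolation guards against undersampled elevations
but cannot create richness outside recorded limits.

Two conventions needed fixing and are deliberate:

* **Snapping.** Raw limits rarely sit on 100-m marks. Lower limits round
  *down* and upper limits round *up* to the nearest mark before clipping to
  the domain. This conservative rule never drops a band the raw range
  touches; the alternative (nearest-mark rounding) can.
* **Trend regression.** The richness–elevation trend is an ordinary
  least-squares polynomial in raw elevation powers. The degree is
  configurable with default 4 — the smallest degree that accommodates a
  low-elevation hump plus a steep upper decline without oscillating on
  ~50 bands — and every report states the degree used. All bands in the
  domain, including zero-richness ones, enter the regression.

## The mid-domain-effect null model

The mid-domain effect (MDE) is the expectation that randomly placing
*cohesive* species ranges inside a bounded domain concentrates range overlap
mid-domain, producing a central richness peak with no environmental input.
`simulate_null()` implements the classic randomization: each species keeps
its empirical range size $k$ (in bands, so the empirical range
size-frequency distribution is used exactly once per simulation — the
"without replacement" scheme), and its start band is drawn uniformly from
the $B-k+1$ feasible positions in a domain of $B$ bands. The default is
10,000 simulations; per-band means and 2.5/97.5 percentile envelopes are
returned. A with-replacement variant (sizes resampled each simulation) is
available behind `replace = TRUE` for sensitivity checks.

Placement is uniform over discrete feasible *start positions*, not over
continuous midpoints: this matches the discrete band system the empirical
profile uses, and it admits a closed form. For band $b$,

$$p(b, k) \;=\; \frac{\min(b,\, B-k+1) - \max(1,\, b-k+1) + 1}{B-k+1},$$

and the expected richness at $b$ is $\sum_i p(b, k_i)$. `expected_richness()`
computes this and serves as the analytic oracle for the Monte-Carlo engine:
the package's tests require agreement within three binomial standard errors
at 10,000 simulations, exact occupancy conservation in every simulation
($\sum_b \text{richness}_b = \sum_i k_i$), symmetry about the domain
midpoint, and a mid-domain maximum. The MDE's explanatory power is then
summarised by the OLS regression of the empirical profile on the null mean
(`fit_mde()`), reported as $R^2$.

The null model validates its input strictly: a range extending outside the
band domain is an error naming the species, not a silent clip — a clipped
range would change the size distribution the null is meant to preserve.

## Grid richness, coverage filtering and hotspots

Occurrence points are assigned to square analysis cells (default 20 km) by
half-open intervals with a top-left origin: a point on a shared edge belongs
to the cell whose left (or top) edge it lies on, so every point has exactly
one cell and edge behaviour is testable. Duplicate records of a species in a
cell count once. Cells with less than half their area inside the study
region are excluded (`filter_cells()`, threshold 0.5, kept when exactly
met); area fractions can come from a mask raster or a region polygon.

Hotspots use the greedy complementarity algorithm: select the cell with the
most species, then repeatedly the cell adding the most species not yet
represented, until all species are covered. Ties are broken by `(row, col)`
ascending — the procedure is deterministic and invariant to input order.
The full greedy order is returned so any prefix can serve as a candidate
reserve set; the first cell(s) are the richness hotspots.

## Impact variables

Five per-cell predictors are assembled at the analysis resolution:

| Variable | Units | Definition |
|---|---|---|
| MAT | °C | mean of temperature pixels in the cell |
| MAP | mm/yr | mean of precipitation pixels |
| PET | mm/yr | mean of potential-evapotranspiration pixels |
| HHET | m | max − min DEM pixel (topographic relief) |
| DIST | index | mean human-footprint change between two years |

Aggregation uses pixel-center membership (a pixel belongs to the cell its
center falls in), the exactly-testable convention matching common zonal
statistics; nodata pixels are excluded and cells with any missing predictor
are dropped from modelling. DIST follows the disturbance semantics: positive
when the footprint *decreased* (undisturbed or restored habitat), negative
when it increased, i.e. DIST = mean(HFI~start~ − HFI~end~); the literal
later-minus-earlier difference is available via `order = "literal"`.
Predictors are standardized to z-scores before modelling so coefficients are
comparable; raw values are retained in all outputs.

Rasters travel as ESRI ASCII grids — a plain-text single-band format chosen
so every artifact in a pipeline run is diffable and portable.

## Richness models

Cell richness is overdispersed count data, so the core model is the NB2
GLM with log link: $y \sim \mathrm{NB}(\mu, \theta)$ with
$\log \mu = \beta_0 + \beta^\top z$ and variance $\mu + \mu^2/\theta$,
$\theta$ estimated by maximum likelihood. AIC is $-2\log L + 2(p+2)$,
counting the intercept and $\theta$. Goodness of fit is reported as
*adjusted explained deviance*, the GLM analogue of adjusted $R^2$:
$D^2 = 1 - D_{res}/D_{null}$ and
$\mathrm{adj}\,D^2 = \left(1 - \frac{n-1}{n-p-1}(1-D^2)\right)\times 100\%$.
This is the only $R^2$-like quantity an NB-GLM natively yields, and reports
label it explicitly to avoid conflation with OLS $R^2$.

Model selection enumerates **all** non-empty predictor subsets ($2^p-1$;
31 for five predictors), ranks by AIC, and names as best the lowest-AIC
model whose predictors all pass the multicollinearity screen
VIF $< 5$, with VIF$_j = 1/(1-R^2_j)$ from regressing predictor $j$ on the
others. Exhaustive enumeration is deterministic and subsumes stepwise
search; an AIC-greedy both-direction stepwise mode is provided for
comparison (`method = "stepwise"`). By default only occupied (non-zero)
cells enter the model, mirroring how presence-only occurrence data define
the response; `include_zeros = TRUE` adds retained empty cells as structural
zeros. The MDE null prediction is never used as a model predictor: as a
pure geometry construct it is independent of the environmental gradients
being tested.

The path model treats the predictors as a freely covarying exogenous block
with richness the single outcome. For this structure the maximum-likelihood
path coefficients coincide with the standardized partial regression
coefficients of the multiple regression of standardized richness on
standardized predictors, which is exactly how `path_model()` computes them,
along with the total $R^2$. No latent variables or multi-equation structures
are modelled; with a single outcome they would add nothing identifiable
here.

## The synthetic landscape generator

Because real occurrence records for systems like this are typically not
redistributable, validation runs on synthetic scenes with stored ground
truth (`simulate_scene()`). The generator emulates the statistical structure
the analysis assumes, at the study's printed magnitudes:

* **Rasters.** A smooth DEM spanning 188–7556 m with a west-high ramp plus
  coherent random texture (sums of random cosine waves); MAT = 22.5 °C −
  0.004 °C/m × elevation plus smooth noise, reproducing extremes near
  −7.4…20.9 °C; MAP rescaled exactly to 430–1785 mm/yr and PET to
  113–1568 mm/yr, both increasing eastward (PET additionally declining with
  elevation); two human-footprint fields on the 0–50 index scale whose
  difference concentrates in the east.
* **Ranges.** 137 species by default. Range sizes are drawn from a
  controllable size-frequency distribution (default lognormal, median
  1500 m, `sdlog` 0.6 — a realistic right-skewed mixture of narrow
  endemics and wide generalists), midpoints uniform over feasible
  positions, limits snapped outward to 100-m marks. The species domain
  defaults to the DEM range snapped inward (200–7500 m) so the elevational
  and spatial layers stay mutually consistent.
* **Occurrences.** Intensity is defined at the cell level, because the
  analysis models cell richness: each 20-km cell's count is drawn from
  NB$(\exp(\beta_0 + \beta^\top z), \theta)$ on its own standardized
  predictors, then that many distinct species are sampled among those whose
  elevational range overlaps the cell's DEM range, each placed uniformly in
  the cell. Defaults: $\beta_0 = \log 4.5$,
  $\beta = (0.10, 0.30, 0.50, 0.15, -0.25)$ for (MAT, MAP, PET, HHET,
  DIST), $\theta = 3$ — strong positive water–energy effects, a negative
  disturbance effect, overdispersed counts, mean occupied-cell richness
  around 5.

Everything is a pure function of the configuration seed; identical seeds
give byte-identical artifacts, including CSV/ASCII-grid output.

The default scene is a 400 × 400 km extent with 4-km pixels, i.e. 400
analysis cells and 25 pixels per cell — large enough for coefficient
recovery within ±3 standard errors and for 31-model selection, small enough
that the full pipeline runs in about a second. What passing tests on such
scenes shows is that the *machinery* is correct: interpolation, null model,
gridding, aggregation and model fitting recover known structure. What they
do not show is robustness to features of real data the generator omits —
spatial sampling bias in herbarium records, coordinate imprecision
(generated points are exact), taxonomic error, range-size measurement
error, spatial autocorrelation of residuals, and irregular study-region
boundaries (the default scene has full cell coverage; coverage filtering is
exercised separately with masks and polygons).

## Numerical choices and degenerate inputs

* Ties in `profile_summary()` (peak/minimum bands) break toward the lowest
  elevation; ties in greedy gain break by cell index.
* Constant responses: a constant richness profile or constant null
  prediction makes $R^2$ undefined; both are reported as 0 with a warning.
  A constant count response yields a flagged degenerate intercept-only NB
  fit rather than an optimizer failure.
* Exact collinearity reports VIF `Inf` with a `collinear` flag instead of a
  numeric overflow.
* The NB deviance satisfies $D_{res} \le D_{null}$ up to IWLS tolerance;
  non-convergence is an error naming the iteration count, and failed subset
  fits are excluded from the ranking with a warning.
* Monte-Carlo confidence intervals are percentile intervals (2.5%, 97.5%)
  across simulations — standard for randomization nulls.
* All RNG flows through per-stage seeds derived from one master seed; no
  hidden entropy.

## Known limitations

* No spatial-autocorrelation correction is applied anywhere; estimates on
  spatially structured data inherit the usual optimistic standard errors.
* The path model is a single-equation standardized regression; it cannot
  express indirect effects between predictors.
* Range interpolation assumes elevational cohesion; disjunct elevational
  distributions are overfilled by construction.
* Raster handling assumes a shared projected CRS and square pixels; there
  is no reprojection engine, only alignment checks.
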