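# richscape

Elevational and spatial species-richness patterns of threatened plants, and
what drives them.

`richscape` is for macroecologists and conservation analysts who have (i) a
table of species elevational limits and (ii) occurrence points over a
projected landscape, and want the standard richness-pattern workflow as
tested, scriptable R functions instead of a GIS click-path:

* **Elevational richness** by range interpolation: a species is assumed
  present in every 100-m band between its recorded limits; bands are
  inclusive 100-m marks, so a 200–4800 m domain has 47 bands. A polynomial
  OLS trend summarises the richness–elevation shape.
* **Mid-domain-effect (MDE) null model**: 10,000 Monte-Carlo randomizations
  that keep each species' empirical range size `k` and place its start band
  uniformly over the `B − k + 1` feasible positions of a `B`-band domain,
  yielding per-band null means and 95% envelopes. The closed-form
  expectation, `E[rich(b)] = Σᵢ (min(b, B−kᵢ+1) − max(1, b−kᵢ+1) + 1)/(B−kᵢ+1)`,
  is implemented alongside as an analytic cross-check. The MDE's explanatory
  power is the `R²` of empirical-on-null OLS.
* **Grid richness and hotspots**: occurrences gridded into 20-km half-open
  cells, low-coverage cells (< 50% in-region area) excluded, and greedy
  complementarity (set-cover) hotspot selection.
* **Impact variables** from rasters: MAT, MAP, PET as per-cell means, HHET
  (habitat heterogeneity) as per-cell elevational relief, DIST as
  human-footprint change with positive = undisturbed/restored.
* **Attribution**: NB2 GLM (log link, variance `μ + μ²/θ`) over all `2⁵ − 1
  = 31` predictor subsets, ranked by AIC (`−2logL + 2(p+2)`) with a VIF < 5
  multicollinearity screen and adjusted explained deviance
  `(1 − ((n−1)/(n−p−1))(1−D²))·100%`; plus a standardized path model whose
  coefficients are the standardized partial regression coefficients of
  richness on the predictor block.
* **A synthetic-landscape generator** with stored ground truth (rasters,
  ranges, occurrences drawn from a known NB model), so the whole pipeline
  can be validated end-to-end with known answers.

## Worked example

A fully synthetic analysis with known truth (β = 0.10 MAT, 0.30 MAP,
0.50 PET, 0.15 HHET, −0.25 DIST on the log scale; θ = 3):

```r
library(richscape)

scene <- simulate_scene(scene_config(seed = 42))
scene
#> <synthetic_scene> 137 species, 2344 occurrences, 20 x 20 analysis cells
#>   DEM 188-7556 m, seed 42

bands   <- build_bands(200, 7500, 100)
profile <- interpolate_richness(scene$ranges, bands)
null    <- simulate_null(scene$ranges, bands, n_sims = 10000, seed = 42)
fit_mde(profile, null)
#> Empirical-vs-null (mid-domain effect) regression
#>   R-squared: 0.972   slope: 1.011   intercept: -0.444
```

Ranges here were *placed at random*, so the geometric null explains almost
everything (R² = 0.97): the profile is pure mid-domain effect, as it should
be. On real data this R² is the share of the elevational pattern explained
by domain geometry alone.

```r
cells <- assign_to_grid(scene$occurrences, scene$grid)
cells
#> <grid_cells> 355 occupied cells, 133 species, richness 1-49
head(hotspot_complementarity(cells), 3)
#>   rank row col richness new_species cum_species
#> 1    1  18  14       49          49          49
#> 2    2  11  17       28          21          70
#> 3    3   8  19       23          11          81

pred <- predictor_table(scene$rasters, scene$grid)
dat  <- merge(as.data.frame(cells), pred, by = c("row", "col"))
z    <- standardize_predictors(dat)
all_subsets(dat$richness, z[c("MAT", "MAP", "PET", "HHET", "DIST")])
#> All-subsets NB-GLM selection: 31 models ranked by AIC
#>  rank                                                         variables k
#>     1 MAT (+0.11), MAP (+0.27), PET (+0.43), HHET (+0.09), DIST (-0.21) 5
#>     2               MAT (+0.12), MAP (+0.29), PET (+0.41), DIST (-0.21) 4
#>     3              MAP (+0.27), PET (+0.49), HHET (+0.10), DIST (-0.21) 4
#>  adj_d2_pct    aic max_vif vif_ok
#>       60.69 1778.6    1.76   TRUE
#>       59.92 1783.5    1.74   TRUE
#>       59.91 1783.5    1.40   TRUE
#> Best model (lowest AIC with all VIF < 5): MAT + MAP + PET + HHET + DIST

path_model(dat$richness, z[c("PET", "MAP", "HHET", "DIST")])
#> Standardized path model (saturated exogenous block)
#>    PET    MAP   HHET   DIST
#>  0.397  0.327  0.056 -0.217
#>   total R-squared: 0.453
```

The selected coefficients carry the generative signs and ordering (PET >
MAP > DIST in magnitude, DIST negative); this fit is on occupied cells only,
while exact ±3-SE coefficient recovery against the stored truth (all 400
cells, truth z-scores) is asserted in the test suite.

The one-shot driver `run_pipeline(run_config(out_dir = "run1", seed = 1))`
executes all six stages and writes every artifact (CSV profiles,
predictions, rankings; JSON reports; ASCII-grid rasters) plus a manifest
with seeds and counts. Identical seeds give byte-identical outputs.

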