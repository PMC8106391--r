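# ecosens

Vegetation sensitivity and memory-effect mapping from monthly raster time
series.

`ecosens` is an R package plus a scripted analysis for quantifying, pixel
by pixel, how strongly vegetation cover responds to short-term climate
variability in dryland basins. From monthly stacks of NDVI, air
temperature, precipitation and land-surface temperature it produces:

* **trend maps** — Mann-Kendall `Zc` and Theil-Sen `beta` on annual NDVI
  composites, with five-class trend maps, slope bands and cover-level
  area fractions;
* **TVDI** — the temperature vegetation dryness index from per-scene
  dry/wet-edge fits in NDVI-LST space (0 = wet edge, 1 = dry edge);
* **memory maps** — the lag-1 coefficient `alpha` of the per-pixel
  anomaly regression
  `NDVI_t = alpha NDVI_{t-1} + beta Tem_t + gamma Pre_t + delta TVDI_t + e_t`,
  classed as weak (`alpha < 0.4`), moderate (`0.4-0.6`) and strong
  (`>= 0.6`) memory;
* **climate weights** — per-pixel relative importances of temperature,
  precipitation and TVDI from principal-components regression
  (components kept at `p < 0.1`), globally rescaled to `[0, 1]` and
  normalized to sum to one;
* **the vegetation sensitivity index (VSI)** — the weighted sum of
  log10 ratios of NDVI variability to each climate variable's
  variability (variability = mean-variance-residual score in `[0, 100]`),
  displayed on a 0 (low) to 100 (high sensitivity) scale.

Because no observational data ship with the package, a seeded synthetic
scene generator (`synth_config()`, `generate_climate_stacks()`,
`generate_ndvi()`) produces stacks with known ground-truth structure —
seasonal cycles, weak trends, elevation gradients, LST data gaps and
AR1-structured NDVI anomalies — so every stage is verified by parameter
recovery. Supporting preprocessing (Savitzky-Golay smoothing,
maximum-value composites, DCT-based penalized-least-squares gap filling
with GCV, nearest-neighbour resampling, low-cover month exclusion) is
included.

## Worked example

The `analysis/` scripts run the reference study — a 30 x 30 synthetic
basin over 2000-2018 — end to end, writing rasters and tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_tvdi.R
Rscript analysis/04_trend.R
Rscript analysis/05_sensitivity.R
```

Stage 4 prints, for the default seed:

```
Area fractions by trend class:
   sig_increase nonsig_increase        no_trend nonsig_decrease    sig_decrease
         0.0544          0.6789          0.0444          0.2122          0.0100
Basin-mean annual NDVI: Zc = 4.69, beta = 0.00063/yr -> sig_increase.
75.11% of vegetated pixels have beta > 0.
```

i.e. the basin-mean greening trend is significant at the 1.96 threshold
and most pixels trend upward — consistent with the weak positive NDVI
trend built into the scene. Stage 5 prints:

```
Memory coefficient alpha: median 0.286 (IQR 0.228-0.372).
Memory-class fractions:
 alpha<0.4    0.4-0.6 alpha>=0.6
    0.7968     0.1515     0.0517
VSI: range [0.0, 100.0], median 72.4; 0.46% of pixels below 30.
```

The fitted memory coefficient is attenuated relative to the generative
`alpha = 0.5` by the observation chain (smoothing, TVDI recomputation,
re-standardization) — see the methods vignette
(`vignettes/vegetation-sensitivity.Rmd`) for why, and for every modelling
choice, default and limitation.

A minimal programmatic run:

```r
library(ecosens)
cfg <- pipeline_config(synth_config(n_rows = 30, n_cols = 30,
                                    n_years = 19, seed = 42))
res <- run_pipeline(cfg, out_dir = "results/run")
range(res$sensitivity$vsi$vsi, na.rm = TRUE)   # 0 100
res$sensitivity$memory$fractions
```

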