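# canopyn

Canopy nitrogen diagnosis for orchard tree crops from fused UAV hyperspectral
and LiDAR data.

## The problem

Nitrogen drives yield and fruit quality in woody crops, but measuring a
tree's nitrogen status destructively (felling, organ separation, Kjeldahl
digestion) is slow and expensive. UAV sensors offer a non-destructive
alternative, with a catch on each side: passive hyperspectral imagery sees
chlorophyll-linked absorption but saturates in dense perennial canopies,
while LiDAR sees three-dimensional structure (and hence biomass) but not
biochemistry. `canopyn` implements the full analysis chain that fuses the
two, for two stage-specific nitrogen targets:

- **CNC** — canopy nitrogen concentration, defined as leaf nitrogen
  concentration (g kg⁻¹): `CNC = NC_leaf`
- **AGNA** — aboveground nitrogen accumulation (g plant⁻¹):
  `AGNA = Σ_o NC_o · M_o` over the four organs o ∈ {leaf, shoot, fruit,
  trunk}, with `NC_o` the organ nitrogen concentration (g kg⁻¹) and `M_o`
  the organ dry mass (kg plant⁻¹)

The package is aimed at agricultural remote-sensing researchers and
methodologists who want a tested, fully reproducible implementation of this
pipeline — including a synthetic-data module that simulates
nitrogen-structured spectra and tree point clouds, so every stage can be
exercised and validated without any field data.

## The method

1. **Spectral chain** — per-tree canopy reflectance on the sensor's 561-band
   grid (400–1000 nm, 1.07 nm interval) is denoised with Savitzky–Golay
   convolution smoothing; the normalized difference spectral index
   `NDSI(λᵢ, λⱼ) = (Rᵢ − Rⱼ)/(Rᵢ + Rⱼ)` is evaluated for **every** band pair
   and scored against the trait (R² of the linear fit, or Spearman rank
   correlation); the maximizing pair is selected per growth stage and flight
   altitude.
2. **Structural chain** — raw point clouds are ground-filtered by
   progressive-densification TIN, height-normalized, rasterized into a
   smoothed canopy maxima model, segmented into individual trees by
   marker-controlled watershed, and summarised per tree as plant height (PH),
   crown diameter (CD, mean of the cardinal crown widths) and canopy volume
   (CV, 3D convex hull).
3. **Fusion and modelling** — the selected NDSI plus PH, CD, CV form the
   feature table (spectra and structure may come from different flight
   altitudes; the optimized configuration pairs 100 m spectra with 60 m
   LiDAR). Four regressors — MLR, PLSR, SVR and RFR (100 trees, minimum
   split 2, minimum leaf 2, maximum depth 3) — are compared under
   leave-one-out cross-validation with
   `R² = 1 − SS_res/SS_tot`, `RMSE = √(Σ(ŷᵢ−yᵢ)²/n)` and
   `MRE = (1/n)Σ|yᵢ−ŷᵢ|/yᵢ`.
4. **Treatment statistics** — one-way ANOVA (also reconstructible from
   published mean ± SD summaries) with Tukey HSD and compact letter
   displays for the fertilization-trial tables.

## A worked example

Plant a known band pair into simulated spectra and let the full-spectrum
screen recover it:

```r
library(canopyn)

sim <- simulate_planted_pair(64, 560, 690, seed = 1)
scr <- band_pair_screen(sim$spectra, sim$trait)
select_best_pair(scr)[, c("lambda_i_nm", "lambda_j_nm", "score")]
#>   lambda_i_nm lambda_j_nm     score
#> 1         559         690 0.9468726
```

The screen lands one grid band (1.07 nm) off the planted 560 nm edge and on
the planted 690 nm band, with R² = 0.95 of the trait variance explained —
the remainder is the simulated sensor noise.

Structural metrics from a simulated tree (3 m tall, 2 m crown, 1.5 m crown
depth; analytic crown volume `(4/3)π·1²·0.75 ≈ 3.14 m³`):

```r
cl <- generate_tree_point_cloud(ph = 3, cd = 2, crown_depth = 1.5, seed = 1)
tree_metrics(cl, "tree_1")
#>   tree_id ph       cd       cv crown_base
#> 1  tree_1  3 1.938377 2.774575   1.505749
```

PH is exact (the crown apex is a deterministic point), CD is within 3% and
CV within 12% of the analytic value at this sampling density — denser clouds
converge to the analytic volume.

Ground-truth nitrogen from organ samples:

```r
organs <- tibble::tibble(
  organ = c("leaf", "shoot", "fruit", "trunk"),
  nc    = c(30, 20, 25, 10),      # g kg-1
  mass  = c(0.5, 0.4, 0.2, 1.0)   # kg plant-1
)
cnc(organs)   #> 30
agna(organs)  #> 38   (15 + 8 + 5 + 10 g plant-1)
```

The whole pipeline, end to end, on the default simulated trial (2 sites ×
2 stages × 4 N rates × 12 trees per cell):

```r
res <- run_all(default_config(seed = 1))
res$results   # 16 rows: stage x trait x {MLR, PLSR, SVR, RFR}
```

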