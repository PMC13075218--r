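---
title: "Methods: canopy nitrogen diagnosis from fused hyperspectral and LiDAR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy nitrogen diagnosis from fused hyperspectral and LiDAR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`canopyn` implements a complete analysis chain for diagnosing the nitrogen
status of orchard tree crops from UAV data: full-spectrum band-pair
screening of hyperspectral reflectance, point-cloud structural metrics, and
leave-one-out cross-validated regression on the fused features. This
vignette is the package's account of the science: the models, their
assumptions, the tunable parameters, what the synthetic-data generator does
and does not emulate, and the numerical choices that were genuinely open.

## Targets and ground truth

Two per-tree nitrogen targets are used, reflecting two complementary
questions — how concentrated is nitrogen in the canopy, and how much
nitrogen has the tree accumulated:

* `CNC = NC_leaf` (g kg⁻¹): leaf nitrogen concentration stands in for the
  canopy, because leaves dominate both the optical signal and the
  physiological interpretation.
* `AGNA = Σ NC_o · M_o` (g plant⁻¹) over leaf, shoot, fruit and trunk.
  The trunk term multiplies the trunk concentration by the **trunk** mass;
  a published form of this equation pairs the trunk concentration with the
  fruit mass, which is dimensionally legal but semantically inconsistent,
  and is corrected here (documented in `agna()`).

Units are fixed throughout: concentrations in g kg⁻¹, dry masses in
kg plant⁻¹, so AGNA lands directly in g plant⁻¹.

## The spectral chain

Reflectance lives on a fixed 561-band grid (400 nm + 1.07 nm × k), the
layout of the push-broom imaging spectrometer the pipeline targets.

**Savitzky–Golay smoothing** (`sg_smooth()`) is a local least-squares
polynomial convolution. Defaults `window = 11`, `polyorder = 2` (≈ 11.8 nm
window) suppress band-wise sensor noise while passing any quadratic signal
untouched; both are recorded in every run manifest because the published
workflows this mirrors rarely state them. Window ends are handled by
polynomial fits on the terminal windows, so polynomials up to the filter
order are reproduced exactly everywhere — a property the test suite asserts
at 1e-10.

**The NDSI screen** (`band_pair_screen()`) evaluates
`(R_i − R_j)/(R_i + R_j)` for every band pair and scores it against the
trait. The normalized-difference form is adopted because it is the universal
two-band index in this literature; its scale-invariance cancels
multiplicative illumination differences between trees. The default score is
the squared Pearson correlation of the linear NDSI–trait fit; Spearman's
rank correlation is available (`stat = "spearman"`) and is the statistic
used for headline reporting, because the index–trait relation is expected to
be monotone but saturating (see the generator section). Pairs with a zero
reflectance sum in some sample are scored on the remaining samples; pairs
with zero NDSI variance score 0 with a warning rather than propagating NaN.
`select_best_pair()` breaks exact ties toward the smallest `λ_i`, then
`λ_j`, making selections deterministic, and reports wavelengths rounded to
integer nm in the conventional "(560, 690)" style.

The screen runs on smoothed spectra pooled by growth stage across sites —
pooling matches how multi-site, multi-year campaigns build one model per
stage — and separately per flight altitude.

## The structural chain

**Ground filtering** (`classify_ground()`) is progressive TIN
densification: seed the triangulation with per-cell minima, then iteratively
accept points whose perpendicular distance to the containing facet and
angles to its vertices fall below thresholds. Defaults — cell 1.0 m,
distance 0.3 m, angle 10° — are the common starting values for orchard-scale
scenes; the originating workflows run this step inside commercial software
without printing parameters, so all three are configurable. Two
implementation details matter: the Delaunay triangulation is built by
Bowyer–Watson insertion (written in-package; no suitable triangulation
dependency is part of the supported stack), and four bounding-box corner
vertices at the elevation of the nearest seed are added so the TIN hull
covers the whole footprint — otherwise edge points can never be evaluated.

**Height normalization** subtracts the TIN elevation; queries outside the
hull extrapolate from the nearest facet with a warning.

**The canopy maxima model** rasterizes per-cell maximum height (default
0.25 m cells), fills empty cells by neighbourhood interpolation and smooths
with a boxcar window (default 3 cells). **Segmentation** floods the inverted
raster from markers — tree apices detected as local maxima above
`min_height = 0.5` m, or supplied coordinates. Cells are visited in
decreasing height order and join the basin of their highest labelled
neighbour, so labels partition the above-threshold cells exactly; markers
below the height threshold yield flagged, empty segments. A
marker-controlled watershed is implemented directly because the available
image-analysis stack exposes only marker-free watershed variants.

**Per-tree metrics** (`tree_metrics()`): PH is the maximum normalized
height; CD averages the east–west and north–south extents of crown points;
CV is the 3D convex-hull volume of crown points, computed by an in-package
incremental hull (again, no hull dependency in the supported stack). The
crown base separating trunk from crown returns is estimated from the
vertical profile — the lowest height bin whose horizontal spread reaches a
quarter of the maximum spread — because a fixed threshold either truncates
short canopies or admits trunk returns, and trunk returns visibly inflate a
convex hull. A fixed `crown_base` can be supplied instead.

Two numerical facts about hull-based crown volume are worth knowing. First,
the hull of a finite sample of a convex body underestimates its volume
(missing caps between hull facets and the surface); second, coordinate
jitter inflates the hull, and the inflation grows with point count because
the hull chases extreme noise draws. At the generator's default return
density (250 points m⁻²) the two effects nearly cancel for realistic crowns
with 0.05 m noise; validation uses that density, plus dense noise-free
clouds against analytic ellipsoid volumes.

## Fusion and modelling

`assemble_features()` joins, per tree, the NDSI at the selected pair
(computed from the chosen hyperspectral altitude) with PH, CD, CV (from the
chosen LiDAR altitude) and one target. The two altitudes are deliberately
independent: the optimized configuration pairs 100 m spectra (larger
footprint averages out leaf-level noise) with 60 m LiDAR (denser point
cloud, better structure).

Model families (`model_spec()`):

* **MLR** — ordinary least squares with intercept.
* **PLSR** — latent-projection regression, default 2 components (the usual
  default for 4 predictors); at full rank it equals OLS, which the test
  suite uses as an oracle.
* **SVR** — RBF kernel, ε-insensitive loss, `C = 10`, `ε = 0.1`, gamma
  `1/(p · var)`, predictors standardized by training-fold statistics only
  (no leakage).
* **RFR** — 100 trees, minimum split 2, minimum leaf 2, maximum depth 3,
  all features considered at each split, bootstrap resampling. These
  hyperparameters are fixed, as stated, rather than tuned.

**LOOCV** (`loocv()`) holds out each tree once and scores the pooled
held-out predictions a single time — per-fold R² is undefined with one
sample. Stochastic families rerun the whole fold loop `repeats` times under
derived seeds, and the across-repeat SD is reported as the "±" spread;
how such spreads were obtained in published tables is generally unstated,
and repeat-spread is the one definition that is computable under LOOCV.
For linear models the fold loop is cross-checked against the closed-form
leave-one-out identity `ŷ₋ᵢ = yᵢ − eᵢ/(1 − hᵢᵢ)` at 1e-8.

**Metrics**: `R² = 1 − SS_res/SS_tot` is primary, because the
variance-ratio form `Σ(ŷᵢ−ȳ)²/Σ(yᵢ−ȳ)²` printed in some sources is only
valid for in-sample OLS; both are always reported (`r2`, `r2_ratio`),
along with RMSE and MRE. Diagnostics: `vif()` (1/(1−R²) of each predictor
on the rest) and `permutation_importance()` (mean R² drop under column
shuffling) — the latter replaces exact SHAP attribution, which is out of
scope.

## What the synthetic generator emulates

The generator exists so that every stage of the chain is testable without
field data. It emulates:

* **The trial design**: 2 sites × 2 stages (vigorous vegetative growth,
  fruit expansion) × 4 N rates (0/150/300/450 kg N ha⁻¹) × 3 replicate
  blocks, 4 trees per block by default. The `table1_calibrated` profile
  draws each cell's biomass, CNC and AGNA from normal laws whose means and
  SDs equal a built-in reference summary of the emulated two-site trial
  (`nitrogen_reference_summary()`), so treatment contrasts — flat CNC at the
  vegetative stage, peak-at-N2 CNC at fruit expansion, biomass rising with
  rate — are reproduced. Trees are drawn iid within a cell (the replicate is
  a blocking label only), which keeps the null ANOVA calibrated at
  tree-level degrees of freedom.
* **Organ partitioning**: organ masses are fixed stage-specific fractions
  of biomass (VGS 0.20/0.30/0.00/0.50, FES 0.25/0.20/0.15/0.40 for
  leaf/shoot/fruit/trunk). Published fractions were not available; these
  values were chosen so that for every reference cell the leaf nitrogen
  stock stays below the AGNA target with margin — a feasibility constraint,
  since the non-leaf organs must carry the remaining (non-negative)
  concentrations. Only the aggregate biomass/CNC/AGNA laws are calibrated;
  the within-tree split is a modelling convenience.
* **Spectra**: a parametric surrogate, not a radiative-transfer model — the
  analysis needs controllable band-level sensitivity, not physical fidelity.
  Visible baseline 0.12 with a green peak at 550 nm; chlorophyll absorption
  wells at ≈450 and ≈670 nm whose depth increases in CNC but **saturates**
  (`2.2 − 11·e^(−0.09·cnc)`); a logistic red edge at ≈715 nm; an NIR plateau
  that increases in canopy density and also saturates (`1 − e^(−3d)`
  scaling). Both saturations encode the optical "saturation effect" of
  dense perennial canopies — the reason rank correlations are preferred for
  reporting and the reason LiDAR fusion helps at all: without them, spectra
  would carry complete, linear information about both chemistry and biomass
  and structural features would be redundant.
* **Altitude effects**: soil fractions 0.05/0.10/0.15 and noise SDs
  0.005/0.008/0.012 at 60/80/100 m, with a soil spectrum brighter than the
  canopy in the visible and dimmer than a dense canopy's NIR plateau — so
  climbing raises visible reflectance and lowers NIR, and higher flights
  are noisier but see the same trees.
* **Point clouds**: ground disc, thin trunk, uniform ellipsoidal crown with
  a deterministic apex at exactly `z = PH`; optional Gaussian jitter; crown
  dimensions tied to biomass by simple allometry (PH ≈ 1.6 + 0.45·B m,
  CD ≈ 1.1 + 0.35·B m, crown depth half of PH) plausible for 8-year orchard
  trees at 2 × 3 m spacing.

It does **not** emulate: real leaf optics or BRDF effects, wind and terrain,
multi-return LiDAR semantics, registration error between sensors, or
spatial autocorrelation between neighbouring trees. Passing tests therefore
demonstrate that the chain is implemented correctly and behaves sensibly
under controlled signal/noise structure — not that any particular accuracy
level would be attained on real orchards.

All randomness flows from one master seed through documented splitting
(`derive_seed(seed, purpose)`), so every artifact is bit-reproducible.

## Model ranking under the calibrated generator

One qualitative claim from the literature this package mirrors — that a
depth-limited random forest dominates MLR, PLSR and SVR on these fused
features — does **not** reproduce under the calibrated generator, and the
corresponding check in the test suite documents that honestly rather than
being weakened. The reason is structural: after band-pair selection the
dominant predictor is a single monotone (if saturating) index, and for such
signals an RBF-kernel SVR and even plain OLS are close to the oracle
regression, while a forest of depth-3 trees pays a piecewise-constant
approximation penalty it cannot recover at these sample sizes. Forest
dominance on real data plausibly rests on features of that data the
surrogate deliberately omits (outliers, registration artifacts,
heteroscedastic shadow effects, site-specific interactions). The
fusion-synergy claim — fused spectral + structural features beat
spectral-only features for nitrogen accumulation — does reproduce robustly
once NIR saturation is in the generator, and is asserted in the suite.

## Problem sizes and numerical choices

Validation runs use the default design (96 trees per stage) for screening
and model comparison, 20-seed repetitions for selection-recovery and
ranking properties, 100-seed repetitions for generator calibration and null
ANOVA checks, and clouds of a few thousand points per tree — sizes chosen so
the full suite exercises every code path at statistically meaningful
replication while remaining comfortable to run on a laptop.

Tie-breaks and degenerate inputs are specified everywhere rather than left
to chance: deterministic band-pair tie-breaking; compact-letter assignment
by insert-and-absorb over groups in descending-mean order; degenerate
geometry (coplanar hulls, collinear triangulations, empty crowns) raises
classed errors naming the offending tree; zero-variance traits are errors,
zero-variance index pairs score zero with a warning. The incremental hull
uses a relative tolerance of 1e-10 of the cloud extent for visibility tests;
the Delaunay incircle predicate uses exact sign evaluation in double
precision, which is adequate for the jittered, metre-scale coordinates the
pipeline encounters.

## Known limitations

* The spectral surrogate's parameter values (well depths, plateau heights,
  soil curve) are calibrated to produce realistic index–trait correlation
  magnitudes, not to any optical database; absolute reflectance levels
  should not be over-interpreted.
* The crown-base profile estimator assumes a laterally narrow trunk and a
  single crown; multi-stemmed or heavily leaning trees would need a supplied
  `crown_base`.
* The TIN point-location step is O(triangles) per query batch; scenes far
  beyond a few tens of thousands of points per tree would want a spatial
  index.
* `combined_structural_correlation()` reports the multiple-correlation
  reading of "PH + CD + CV vs trait" (trait regressed on the triplet, rank
  correlation of fit to trait); per-metric correlations are available via
  `method = "individual"` since the combined definition is one plausible
  reading of how such a value is usually printed.
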