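---
title: "Quantifying urban natural space against policy targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying urban natural space against policy targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbannature)
```

## The problem

Urban green and blue space is associated with lower mortality and better
mental health, and health studies quantify that exposure almost exclusively
with NDVI, the normalized difference vegetation index. Policy targets,
however, are written in areas and access shares — the C40 Urban Nature
Declaration asks that 30–40% of a city's area be green (*Quality Total
Cover*, QTC) and that 70% of its population live within a 15-minute walk of
green or blue space (*Equitable Spatial Distribution*, ESD). `urbannature`
evaluates a city against both targets from two 10 m rasters (a WorldCover-style
categorical landcover layer and per-date NIR/red reflectance bands), a 100 m
adult population raster and a boundary mask, and then converts each target
into a city-specific NDVI level that can be plugged into NDVI-based
exposure–response functions.

## The measurement model

**NDVI and compositing.** Per cell, $\mathrm{NDVI} = (\mathrm{NIR} -
\mathrm{VIS})/(\mathrm{NIR} + \mathrm{VIS})$, which is invariant to the
band scaling (digital numbers or reflectance floats). The annual composite
takes the per-cell *maximum* across all acquisition dates. This single
choice handles clouds (which depress NDVI) and hemispheric seasonality
(each pixel is observed at its greenest), at the cost of measuring peak
rather than average greenness; that bias is shared by the actual and the
target NDVI levels, so differences between them are less affected.

**Binary layers.** Greenspace is the union of the seven vegetated WorldCover
classes — trees, shrubland, grassland, cropland, herbaceous wetland,
mangroves, moss/lichen; built-up, bare/sparse, snow/ice and open water are
excluded. Natural space adds open water. The *natural-space NDVI* layer
fuses blue space into the continuous metric by setting water cells to 1
(the maximum), and likewise cells whose composite NDVI is negative —
residual cloud or unmapped water. The class list is configurable
(`worldcover_scheme()`); permeable-but-unvegetated surfaces are deliberately
not counted as green by default.

**Aggregation.** All 10 m binary layers aggregate to 100 m by the
area-weighted mean: each coarse cell is the fraction of its valid fine cells
with the property. The 100 m grid is defined by partitioning the 10 m grid
into 10 × 10 blocks anchored at the raster origin, and the population raster
must arrive on that same grid. Partial edge blocks average over the cells
that exist; a coarse cell is nodata only if its whole block is. City
summaries are plain means over the 100 m cells whose (binary) mask cell is
inside the boundary — there is no fractional boundary weighting.

**Access (ESD).** On the 10 m natural mask: (1) connected patches smaller
than 0.5 ha (5,000 m², i.e. 50 cells) are removed — a public-greenspace
minimum that excludes most private lawns; (2) each cell is flagged when the
*total* remaining natural area within a Euclidean 1,000 m buffer of its
centre reaches 0.5 ha; (3) flags aggregate to 100 m fractions; (4) the
population-weighted mean $\sum_i p_i a_i / \sum_i p_i$ over city cells is
the share of people with walkable access. Patch filtering and buffering run
on the full raster, not the masked subset, so a park just outside the
boundary still serves residents near the edge.

**Target conversion.** Over the city's 100 m cells, an ordinary least
squares fit of cell mean NDVI on cell green fraction gives the QTC
conversion; predictions at green fractions 0.30 and 0.40 are the NDVI
equivalents of the target range, and predictions at 0.75, 0.90 and 1.00 are
candidate thresholds for calling a 10 m pixel "green" on the NDVI scale. The
0.75 prediction is the default threshold (`threshold_level`), the level at
which the downstream access models fit best. Thresholding the natural-space
NDVI layer (water, at fused value 1, always passes) and repeating the
patch/buffer/aggregation chain yields an NDVI-based access layer; a second
OLS with the NDVI-based fraction as response and the landcover-based
fraction as predictor is evaluated at 0.70 to give the ESD equivalent.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_patch_m2` | 5,000 | m² | WHO 0.5 ha public-greenspace unit |
| `buffer_m` | 1,000 | m | ~15-minute walk (guideline: 1,080 m in 15 min) |
| `qtc_range` | 0.30–0.40 | share | QTC target range |
| `esd_threshold` | 0.70 | share | ESD population share |
| `threshold_level` | 0.75 | share | green level defining the NDVI threshold |
| `connectivity` | 8 | — | diagonal touching counts as contiguous |

All comparisons against targets and thresholds are inclusive (`>=`): a city
at exactly 30% green passes, a pixel exactly at the NDVI threshold is green.

## Design choices where the design was open

* **Regression direction.** The QTC model is used exclusively to predict an
  NDVI level from a green-area share, so NDVI is the response. The ESD model
  treats landcover access as the predictor of the NDVI-based proximity
  measure. Both transposed variants are available
  (`direction = "green_on_ndvi"`, `"lc_on_ndvi"`); for QTC the transposed
  reading inverts the fitted line to recover an NDVI level, which is the
  only behavioural difference.
* **RMSE denominator** is $n$ (a plain residual root-mean-square, matching
  the interpretation "predictions differ from actual values by RMSE"), not
  $n-2$; switchable in `fit_ols()`.
* **Degenerate fits.** A constant predictor (a fully green or fully built
  city) is an error in `convert_qtc()`/`convert_esd()`; `run_pipeline()`
  downgrades it to a warning and reports the conversion as missing while
  keeping metrics and target evaluation, which remain well defined. A
  constant *response* yields $R^2 = 0$ with a warning rather than 0/0.
* **Buffer semantics.** The ≥ 0.5 ha condition applies to the total filtered
  natural area in the buffer, not to whole-patch containment — slivers of
  large patches count. The kernel is the discrete disk of cell centres
  within `buffer_m` of the focal centre, focal cell included; area outside
  the raster contributes nothing.
* **Patch connectivity** defaults to 8 (the more inclusive reading of
  "contiguous"); 4 is available everywhere.
* **NDVI edge cases.** `nir + vis = 0` gives nodata (undefined ratio) rather
  than 0; compositing usually fills such cells. Out-of-range NDVI
  predictions from the conversion are reported unclamped, with a warning.
* **Raster format.** Grids are read and written as single-band Esri ASCII
  grids in a projected metre CRS, with the CRS tag carried opaquely in a
  `.prj` sidecar; mismatched tags, misaligned grids and geographic
  (degree) systems are errors. The pipeline never reprojects or resamples.

## What the synthetic city emulates

`generate_city()` draws, from one seed (all randomness flows through it; the
caller's RNG state is untouched):

* **Landcover**: a Gaussian random field (FFT-smoothed white noise,
  correlation length 60 cells = 600 m by default) tilted by a radial
  *urban-core gradient* (`core_gradient = 2`) and sliced at the mixture
  quantiles, so built-up and bare classes concentrate centrally and
  vegetation peripherally while global class proportions equal the mixture
  exactly. The default mixture (43% green, 4% water, 43% built-up) matches
  the magnitude of green and natural area shares typical of large cities.
  Contiguous water bodies are stamped as disks. The gradient matters: a
  stationary field at city scale puts a ≥ 0.5 ha patch within 1 km of
  everywhere, making access identically 1 and the ESD regression degenerate;
  real cities have green-poor cores.
* **Reflectance bands**, per date: target NDVI = class mean + correlated
  noise (sd 0.05) − seasonal depression (0 at the peak date, up to 0.3),
  with cloud dropouts (probability 0.10 per cell-date) depressing NDVI by
  0.8. Bands are synthesised as `nir = (1+v)/2`, `vis = (1−v)/2`, so
  `compute_ndvi()` recovers the target field exactly (to floating-point
  rounding) and reflectances stay in [0, 1]. Clouds are depressions, not
  nodata, because the pipeline removes them by max-compositing, not masking.
* **Population** at 100 m: proportional to (built-up fraction + 0.01)²
  with lognormal noise, zero outside the boundary, normalised to a 500,000
  adult total. Placing population directly at 100 m mirrors the resolution
  of gridded population products.
* **Boundary**: a radially tapering score roughened by a correlated field;
  the mask covers 60% of the grid and is expanded block-wise so the 10 m and
  100 m masks are exactly consistent.

`stamp_geometry()` overwrites disks or strips of known area (exactly
`round(size_m2 / 100)` cells at 10 m) with one class and a noise- and
cloud-free NDVI, giving fixtures whose patch filtering and access geometry
are known analytically.

What it does **not** emulate: atmospheric effects and sensor noise,
georeferencing error, spatially coherent cloud fields, landcover
misclassification (WorldCover is ~74% accurate; the pipeline treats it as
truth), demographic structure beyond a single adult surface, and the
idiosyncratic geography of any real city. Passing tests therefore
demonstrate the correctness of the algorithms and the statistical machinery
under controlled structure — not the accuracy of any particular real-city
estimate.

## Numerical and testing notes

Patch labelling (BFS over 4- or 8-neighbourhoods) and the circular focal
sum (per-row chord widths over row prefix sums, $O(n \cdot k)$ for kernel
height $k$) are compiled kernels; both are verified cell-for-cell against
naive R re-derivations — flood fill and all-pairs distance counting — on
batches of random 50 × 50 grids. OLS goes through `stats::lm()` and is
checked against hand-coded normal equations at $10^{-10}$, and $R^2$
against the squared Pearson correlation. Parameter recovery uses 20
simulated cities of 10,000 100 m cells with a known linear NDVI–green
relation (intercept 0.1, slope 0.5, noise sd 0.05); the prediction at 30%
green is required to land within ±0.01 of the true 0.25 on average, within
twice the analytic prediction standard error per city, and within twice the
mean fitted-value standard error in aggregate. End-to-end determinism and
scale are exercised on a 2,000 × 2,000-cell (20 × 20 km) city, which runs
the full pipeline in well under five minutes on one CPU and produces
byte-identical reports across repeated runs; routine examples in the test
suite use 100–1,000-cell grids so the whole suite stays fast.

## Known limitations

* The ESD conversion relates two access fractions; mapping its prediction
  at 0.70 onto a single "natural-space NDVI value" inherits the ambiguity of
  that construction. Alternative readings (predicting cell NDVI from access,
  or inverting the threshold relation) are deliberately not asserted.
* Access is Euclidean-buffer-based; street networks, barriers and land
  tenure (public vs private) are out of scope, as are cycling-speed buffers.
* City means treat every masked 100 m cell equally; cells partially nodata
  at 10 m enter with the mean over their valid fine cells.
* OLS is unweighted with no spatial autocorrelation correction; standard
  errors of the conversion are not propagated into the reported NDVI
  equivalents.
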