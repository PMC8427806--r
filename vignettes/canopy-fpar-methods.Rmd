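---
title: "Canopy profile features and fPAR-based yield calibration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy profile features and fPAR-based yield calibration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyfpar)
```

## The problem

Midday canopy light interception — fractional photosynthetically active
radiation, fPAR — is the primary determinant of potential yield in nut
orchards. It is conventionally measured with a mobile lightbar (an array of
PAR quantum sensors driven beneath the canopy around solar noon), which is
slow, constrained to a ±1 h window, and only resolves rows or blocks. This
package implements the aerial alternative: a photogrammetric digital surface
model (DSM) of the orchard is combined with a parametric planting-grid
layout to produce per-tree canopy profile features, of which **canopy
cover** — the fraction of each tree's allocated ground area covered by its
canopy footprint — serves as the fPAR estimate. The statistical layer then
calibrates that estimate against lightbar fPAR and converts published
potential-yield ratios into calibrated ("adjusted") per-date yield models.

## The planting grid

The orchard is modelled as a rigid grid anchored by three tree centers at
orchard corners: `p1`→`p2` spans the along-row direction and `p1`→`p3` the
cross-row direction. The second direction is orthogonalized against the
first (Gram–Schmidt), and the two raw directions must be perpendicular
within a tolerance (default 5°; the perpendicularity of a real planting is
never exact, and a wrong corner point should fail loudly rather than shear
every cell). The corner points anchor only *directions*: the grid positions
come from the row/tree counts and spacings, so a mis-surveyed far corner
cannot stretch the grid.

Tree `(r, t)` (0-based) sits at
`origin + u2·(r·row_spacing) + u1·(t·tree_spacing + δ(r))`, with `δ(r) = 0`
for the square pattern and half the tree spacing on shifted rows of the
offset pattern. Which parity shifts is configurable (`offset_parity`,
default odd rows) because field conventions differ. Each tree owns a
rectangular **allocated cell** of exactly `tree_spacing × row_spacing`
centered on it; cells tile the orchard without overlap. Inter-planted or
missing trees are handled by an exclusion list: the cell stays in the grid
(its area is still allocated) but the site is dropped from feature tables.

Pixel membership in a cell is decided by the pixel *center* under a
half-open convention (lower edge inclusive in both frame coordinates), so a
pixel on a shared cell boundary belongs to exactly one tree and footprints
never double-count.

## Terrain: from DSM to above-ground heights

Tree/ground separation uses surface slope: crowns present steep flanks,
ground does not.

1. **Slope** is computed by Horn's 8-neighbor finite differences on the 3×3
   window — the common default of terrain libraries — in degrees, with edge
   replication at borders. Nodata propagates through the window.
2. **Tree mask**: pixels with slope strictly greater than 20° (the default
   threshold) are trees. No smoothing is applied before thresholding.
3. **Closing**: crown interiors near the apex are flatter than 20° and
   punch holes in the mask, so a morphological closing with a circular
   element (default diameter 50 px, ~0.8 m at a 1.6 cm ground sampling
   distance) fills them. The element contains every integer offset within
   `diameter/2` of the center; both dilation and erosion treat pixels
   beyond the raster as background (the raster is embedded in the integer
   plane), which makes the closing extensive and idempotent — properties
   the tests assert. The implementation uses an exact Euclidean
   distance transform with integer squared distances, so masks are
   bit-stable across platforms. A warning is issued when the mask touches
   the raster edge, where any convention biases the result.
4. **Ground extraction and infill**: the closed mask is inverted to keep
   ground pixels, and the gaps under crowns are filled by nearest-neighbor
   interpolation — each gap takes the elevation of the Euclidean-nearest
   ground pixel, with equidistant ties broken deterministically by the
   lowest column-major linear index. Nearest-neighbor (rather than a
   smoothing interpolant) cannot hallucinate elevations outside the
   observed ground range; its error under a crown is bounded by the true
   ground relief across that crown, which the test suite asserts on
   generated scenes.
5. **Normalization**: above-ground height is `max(DSM − DEM, 0)`. Negative
   differences are physically meaningless (they arise where the
   interpolated DEM sits marginally above the DSM) and would corrupt the
   volume index, so they are clamped.

The closing element is specified in pixels, following the convention of the
mask-processing step it implements; because it corresponds to a *physical*
hole size (~0.8 m), analyses at other resolutions should scale
`closing_diameter_px` to keep the metric diameter, which is what the test
scenes do.

## Canopy features

Canopy pixels are those with above-ground height ≥ 0.5 m. The threshold is
read as inclusive ("a minimum elevation of 0.5 m"); the choice is
observable only on pixels exactly at 0.5 m and is pinned by a test. Per
tree, clipped to its allocated cell:

- **footprint area** = `n_canopy_px × pixel_size²`. The raster count is
  the area authority; exported polygon outlines are GIS artifacts, because
  any contour simplification changes polygon area in unspecified ways while
  the pixel count is resolution-exact.
- **canopy cover (%)** = `100 × footprint / allocated` — the fPAR
  estimate.
- **canopy volume index (m³)** = `Σ pixel_area × height` over footprint
  pixels (post-clipping, consistent with per-tree accounting).
- **mean / max canopy height** over footprint pixels; zeros when the tree
  has no canopy pixels.

Crowns that merge across trees are split purely by allocated-cell geometry
— no watershed or marker segmentation — which matches how dense plantings
are handled by the clipping description this pipeline follows. Block- and
row-level tables pool footprints over pooled allocated area
(`100·Σfoot/Σalloc`), sum volumes, area-weight mean heights, and take the
max of maxima; with equal cells this equals the mean of member covers.

In principle pixel-center counting in a rotated cell can overshoot the cell
area by a boundary ring; footprint area is therefore capped at the
allocated area so cover never exceeds 100%. On the test scenes the cap
never fires.

## Statistical layer

- **Lightbar fPAR**: `1 − PAR_below/PAR_above`, clamped to [0, 1] with a
  warning (below > above occurs only through sensor noise). Fractions are
  converted to percent before calibration so both fPAR estimates share
  units.
- **Zero-intercept calibration**: `b = Σxy/Σx²` with standard error
  `sqrt(RSS/((n−1)Σx²))` and a two-sided t test of `b = 1` on `n − 1`
  degrees of freedom (one fitted parameter). Whether the through-origin R²
  should use the centered or uncentered total sum of squares is a genuine
  convention split, so both are computed and labelled
  (`r2_centered`, `r2_uncentered`); neither is silently preferred.
- **Calibration statistics**: OLS fit, R² (= Pearson r², asserted), RMSE to
  the fitted line and RMSE to the 1:1 line. Both RMSEs use denominator `n`:
  the 1:1 line has no fitted parameters, and using `n` for both keeps them
  comparable.
- **Predictive R²** = `1 − PRESS/SST`, with PRESS computed by literal
  leave-one-out refits. At calibration scale (tens of rows) the `O(n)`
  refits cost nothing and the code states exactly what is computed; the
  hat-matrix shortcut `Σ(ê/(1−h))²` is asserted equal in the tests rather
  than trusted in the implementation.
- **Potential yield**: `Y = ratio × fPAR%`, with published base ratios
  57.90 (all varieties) and 57.70 (single-variety scope) lb·acre⁻¹ per
  %fPAR. The **adjusted ratio** multiplies the base ratio by the
  zero-intercept calibration slope; display rounding is half-up to 2
  decimals (`round_half_up()`), since banker's rounding would disagree with
  conventionally printed tables at exact halves.
- **Yield regression**: OLS of yield on fPAR% with the same fit statistics,
  a 95% CI on the slope, and residual diagnostics about the potential line
  when a ratio is supplied.

All yield quantities are kept in lb·acre⁻¹ — the unit of the published
ratios — with `lb_acre_to_kg_ha()` provided for SI reporting.

## The synthetic-orchard generator

Real orchard imagery cannot ship with the package, so validation rests on
generated scenes with closed-form truth. A scene is a planar (optionally
sinusoidal) ground surface plus parametric crown solids at the grid sites,
sampled at a chosen pixel size, with optional i.i.d. Gaussian elevation
noise under a fixed seed (fixed seed ⇒ byte-identical rasters, asserted).
The default crown is a **hemiellipsoid** (radius `r`, apex `h`): its height
field `h·sqrt(1−(d/r)²)`, solid volume `(2/3)πr²h`, and cut-contour area
`πr²(1−(c/h)²)` at height `c` are all closed forms, which makes it the
right oracle shape; a spherical cap is offered for asymmetric profiles.
Overlapping crowns combine by max, as a surface model sees only the top
surface. Defaults — `r = 2` m, `h = 3.5` m crowns on 5–6 m spacings,
0.05–0.1 m pixels, noise-free unless stated — describe a mature,
well-managed nut orchard at typical drone-survey resolution.

Companion generators emulate the ground-truth tables: per-row lightbar
records (`fpar = bias × true mean cover + noise`, with raw PAR pairs
back-computed from a nominal above-canopy PPFD) and per-tree yield records
(`yield = attainment × ratio × cover + noise`, floored at 0, reflecting
actual yields sitting below the potential line). With zero noise these
invert exactly: the calibration slope recovers `1/bias` and the
yield-vs-potential slope recovers the attainment fraction — both asserted
to tight tolerances.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: spatially correlated photogrammetric artifacts
(doming, melt-in between adjacent crowns), within-crown height texture and
real holes, variety-dependent crown asymmetry, and lightbar georeferencing
error. The noise model is i.i.d. per pixel, which at high resolution
produces unrealistically rough slope fields; noisy-scene tests therefore
use small noise standard deviations (≤ 0.03 m).

## Numerical choices and degenerate inputs

- Distance computations (closing, infill) compare exact integer squared
  distances (`4·d² ≤ diameter²`), never floating-point radii.
- Nearest-neighbor ties: lowest column-major linear index, documented and
  tested, so results are identical across platforms.
- Collinear corner points, all-nodata rasters, a mask covering every pixel,
  zero variance in a calibration series, and `Σx² = 0` in a zero-intercept
  fit are all hard errors with messages naming the problem; an allocated
  cell falling outside the raster is a per-site `NA` with a warning, and
  the pipeline continues.
- Negative AGL heights are clamped to 0; heights are validated ≥ 0 on
  construction of a `HEIGHT_AGL` raster.

## Problem sizes used by the test and validation suites

Synthetic validation scenes are 2–4 rows × 2–4 trees at 0.05–0.2 m pixels
(up to ~460 × 400 px), which resolves the 2 m reference crowns at
`pixel_size ≤ r/20` — the regime where the discretization bands (±1.5
percentage points of cover, ±2% of volume) are meaningful. The stochastic
slope-recovery check runs 200 replicates of a 26-row regression. These
sizes exercise every code path while keeping the whole suite near ten
seconds; the geometry, not the raster size, is what the assertions depend
on.

## Known limitations

- The slope threshold (20°) fails on very flat, spreading canopies and on
  steep terrain approaching the threshold; the pipeline refuses nothing
  here — the threshold is a parameter, and terrain steeper than ~20° breaks
  the tree/ground separation assumption outright.
- Rasters must be in planar projected meters; geographic coordinates are
  not detected, only documented as unsupported.
- The ESRI ASCII grid is the raster exchange format; it is lossless for the
  package's purposes but verbose for very large surveys.
- Canopy cover saturates as crowns fill their cells, so its relationship to
  fPAR flattens in hedgerow-like plantings; the volume index carries the
  extra information but correlates less well with lightbar fPAR.
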