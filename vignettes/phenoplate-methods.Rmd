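---
title: "Measuring plantlet size, shape and color from plate photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring plantlet size, shape and color from plate photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoplate)
library(dplyr)
```

## The measurement model

A young Arabidopsis rosette is close to a flat, two-dimensional object, so
its projected area in a top-down photograph is proportional to its biomass.
`phenoplate` exploits this: plants grown in an m × n matrix on agar plates
over a white background are photographed repeatedly, and every photograph is
reduced to one record per grid cell with

* **pixel area** — the count of plant-foreground pixels in the cell;
* **convex area and convex ratio** — the pixel count of the filled convex
  hull and 100·area/convex area (%). A compact rosette scores near 100 %;
  elongated petioles or narrow leaves leave empty wedges inside the hull
  and depress the ratio, which is how shape mutants (e.g. phytochrome-B
  loss) are distinguished from the wild type even at similar convex area;
* **mean unwrapped hue** — the color summary that carries the pigment
  signal;
* calibrated **fresh weight**, **chlorophyll** and **anthocyanin**
  estimates, when linear calibration models are supplied.

The package assumes 8-bit RGB input, a near-white background, and that
individual plants stay separated; once rosettes touch, cell truncation
makes areas unreliable (records carry an `EDGE_TOUCH` warning code, and in
practice growth is monitored for about two weeks at most).

## Segmentation: the two-threshold rule

After conversion to HSV (hexcone transform; hue in [0, 1)), a pixel is
plant foreground when

* saturation ≥ `green_threshold` (default **0.25**), and
* luma = (0.299 R + 0.587 G + 0.114 B)/255 ≤ `gray_threshold` (default
  **0.95**).

The white background is simultaneously unsaturated and bright, so either
test alone removes most of it; the conjunction is robust to both colored
reflections (caught by the luma test) and gray shadows (caught by the
saturation test). Interactive tools let an operator tune two sliders per
session; a batch tool needs a deterministic rule, so the two defaults were
fixed once against synthetic plates spanning the realistic hue band and are
exposed as configuration for unusual lighting.

Two clean-up steps replace interactive mask editing: connected components
smaller than `min_object_px` are removed (default 50 px at the 3000 × 4000
reference frame, scaled by actual image area — condensation droplets and
sensor noise are far below this; a germinated seedling is above it), and
holes inside the surviving objects (specular highlights on leaves) are
filled. Both steps preserve the monotonicity of the thresholds: tightening
either threshold can only shrink the final mask, which the test suite
checks as a property.

Foreground is partitioned by splitting the analysis rectangle as evenly as
integer division allows (the first cells on each axis absorb remainder
pixels), with coordinates 0-based and rectangles half-open, cells in
row-major order. Plants crossing a boundary are truncated at it.
Region-of-interest polygons (`refine_roi()`) intersect a cell's mask with a
rasterized polygon (pixel-center-in-polygon, boundary inclusive) when
manual separation is unavoidable.

## Shape: the pixel-fill convex hull

`convex_metrics()` uses a *pixel-fill* hull convention: the convex area is
the number of lattice points (pixel centers) inside or on the convex hull
polygon of the mask's pixel centers. Under this convention the hull of a
filled rectangle is exactly the rectangle, so convex shapes score a ratio
of exactly 100 % — the natural anchor for interpreting the scale.
Degenerate masks are defined consistently: a single pixel has convex area
1; collinear pixels get the lattice points on their extreme segment
(gcd + 1). The implementation (extreme points via `chull()`, then a
half-plane membership test oriented by the shoelace sign) is validated in
the tests against an O(n³) brute-force oracle — membership via
Carathéodory triangles — on exhaustive small windows, and against a Pick's
theorem count for a plus-shaped mask.

## Color: unwrapped hue and linear pigment models

Hue is an angle, and plant-relevant colors straddle its wrap point: healthy
green sits near 0.15–0.25, while anthocyanin accumulation shifts leaves
through turquoise toward red, i.e. raw hues just *below 1*. Unwrapping
(h → h − 1 for h > 0.5) maps those reds to small negative values, so the
biologically meaningful band of roughly −0.02…0.24 becomes one continuous
linear axis. Over this narrow band the arithmetic mean of unwrapped hue is
both continuous and linear, which has a convenient consequence: averaging
hue and then applying a linear calibration equals converting per pixel and
then averaging. Circular statistics would be more general but would break
exactly this composability, which is why they are deliberately not used.

The pigment models are ordinary least-squares lines, fitted by the user
from plants that were photographed and then assayed chemically:

* **hue → chlorophyll (µg/pixel)**: positive slope; the linear relation
  holds for 0.2–1.0 µg/pixel, and predictions outside that response range
  are flagged (`OUT_OF_RANGE_CHL`), not silently trusted. (Per fresh
  weight the relation saturates, which is why the per-pixel response is
  the calibrated quantity.)
* **hue → anthocyanin**: negative slope (reverse correlation); a fitted
  non-negative slope is accepted but warned about, since it indicates a
  calibration that contradicts the pigment's optics.

No default pigment models ship with the package: hue depends on the light
source, camera and species, so calibration is per-setup by design. The
`inst/extdata` demo calibration is labelled synthetic and exists only to
make examples runnable. Negative concentration predictions are clipped to
zero with a `NEGATIVE_CLIPPED` warning — concentrations are physical.

Fresh weight uses the same machinery on pixel area, normalised to the
3000 × 4000 reference frame linearly in total pixel count (the scale
factor is explicit: `area_px · 12e6 / image_px_total`). Calibrations from
200–300 plantlets give stable slopes; fewer than 200 pairs triggers
`SMALL_N_CALIB`. A typical reference-frame slope is about 1/1600 mg per
pixel.

## Reference chemistry

The calibration truth comes from two standard assays implemented exactly
as printed in the spectrophotometry literature:

* chlorophyll/carotenoids from 95 % ethanol extracts:
  Chl a = 13.36·A664.1 − 5.19·A648.6, Chl b = 27.43·A648.6 − 8.12·A664.1,
  carotenoids = (1000·A470 − 2.13·Chl a − 97.64·Chl b)/209, total = a + b
  (an exact identity in the code). Readings outside the reliable OD window
  0.3–0.8 are flagged. The ethanol extract volume is not standardised, so
  per-fresh-weight chlorophyll is computed only when the user supplies it.
* monomeric anthocyanin by the pH differential:
  Adiff = (A520 − A700)pH1.0 − (A520 − A700)pH4.5, concentration =
  Adiff × 83.5 mg/L. The 83.5 factor is used exactly as printed, and is
  assumed to already fold in the assay's molar absorptivity and the 5×
  buffer dilution (100 µL sample + 400 µL buffer); per-fresh-weight values
  use the 200 µL/plant extraction volume. A negative Adiff almost always
  means swapped buffers and is clipped to zero with a flag.

## Growth rates

`growth_rate()` implements exponential regression in its log-linear form:
ln(area) = a + b·t by OLS, returning exp(b) — the per-day growth factor, in
the same convention as spreadsheet exponential-regression functions. This
makes the estimate invariant to rescaling all areas (calibration changes)
and equivariant under time-origin shifts, both covered by property tests.
Zero-area observations are rejected rather than fudged: an empty cell is
missing data, not a measurement of zero biomass.

## The synthetic plate generator

`render_plate()` draws per-cell blobs — disks, squares, plus signs,
five-pointed stars, or absences — of controlled target area, hue,
saturation and value on a near-white background (default RGB 252,252,252:
saturation 0, luma 0.988). It emulates exactly the features the pipeline
keys on: background/foreground contrast in saturation and luma, controlled
pixel area, hull convexity (plus ≈ 54 %, star ≈ 60–80 %, disk ≈ 100 %),
and hue, including negative unwrapped hues for anthocyanin scenarios.

Design choices:

* **Ground truth is raster-derived**, not analytic: the truth table counts
  pixels of the very raster that was drawn, so area comparisons in tests
  are exact for squares and tolerance-free against the raster for all
  shapes; the analytic target is only approximated by rasterization
  (within ~2 % for disks of radius ≥ 20 px).
* **True mean hue is the hue of the 8-bit-quantized color**, so hue
  recovery is asserted to machine precision against truth and within
  1/255 against the requested hue.
* **Noise and vignetting are off by default** (σ = 2/255 per channel and
  10 % corner darkening when enabled) so exactness tests stay exact;
  robustness tests switch them on explicitly. Rendering is deterministic
  given the spec's seed, and the noise generator restores the caller's RNG
  state.
* **Default frame 750 × 1000 px** (1/16 of the reference frame): large
  enough for realistic per-cell geometry at 6 × 6, small enough that the
  full validation suite runs in seconds. Acceptance-style batch checks use
  smaller frames still (120 × 120) since they exercise counting contracts,
  not geometry.

What the generator does *not* emulate — real leaf morphology, shadows, lid
condensation, root show-through, touching rosettes — bounds what green
tests prove: they validate the measurement pipeline, not the photography.
On real images the operator still owes the method a sane grid, lighting,
and per-setup calibrations.

## Numerical and interface conventions

* Rectangles are 0-based half-open; cells are row-major; rows are labelled
  by genotype.
* Half-plane hull tests use an absolute ε of 1e-9 on cross products;
  boundary pixels count as inside (consistent with the pixel-fill
  convention).
* A constant-response fit reports R² = 0 with a warning; a constant
  predictor is an error (no slope is identifiable).
* Warning codes are stable strings (`EMPTY_CELL`, `EDGE_TOUCH`,
  `OUT_OF_RANGE_CHL`, `NEGATIVE_CLIPPED`, `SMALL_N_CALIB`), accumulated
  per record and exported verbatim; per-cell problems never abort a plate,
  and per-image failures never abort a batch.
* Workbook export uses SpreadsheetML 2003 XML — a plain-text Excel dialect
  — with one worksheet per image (names truncated to Excel's 31-character
  limit) plus a combined sheet; numeric cells are typed numeric and `NA`
  becomes an empty cell. A tidy CSV twin carries the same records, and the
  CSV round trip is lossless at 1e-9 relative tolerance.

## Known limitations

* Segmentation has no shadow or specular model beyond the luma threshold
  and hole filling; strongly colored backgrounds defeat it.
* The per-pixel pigment models are linear by construction and calibrated
  over a band; extrapolation is flagged, not prevented.
* EXIF orientation is not interpreted; images are analyzed as decoded.
* Plants crossing cell boundaries are truncated; the tool flags but does
  not automatically separate touching rosettes.

## A compact end-to-end run

```{r example, eval = FALSE}
g <- grid_spec(6, 6, row_names = paste0("geno", 1:6))
base <- plate_spec(grid = g, plants = plant_layout(g, shape = "disk",
                                                   area_px = 1500, hue = 0.21))
series <- render_timeseries(base, growth_factor = 1.3, days = seq(0, 12, 3))
records <- purrr::imap(series, \(s, nm) {
  analyze_plate(s$image, g, image_id = nm) |>
    dplyr::mutate(time = as.numeric(sub("day", "", nm)))
}) |> dplyr::bind_rows()
growth_rates(records, time = time, area = area_px, row_name)
```
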