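# phenoplate

Affordable, non-destructive phenotyping of in-vitro grown plantlets from
ordinary color photographs. Plants (typically *Arabidopsis thaliana*
rosettes) are grown in a grid on agar plates over a white background and
photographed repeatedly with a standard digital camera; `phenoplate` turns
each photograph into one quantitative record per plant — size, shape and
color — and converts color to calibrated pigment contents. It replaces
destructive endpoint assays (weighing, chlorophyll extraction) for routine
growth and stress experiments, at the cost of a one-time calibration.

## Method

For each plate image (reference frame 3000 × 4000 px):

1. **Segmentation.** The image is converted to HSV. A pixel is plant
   foreground when its saturation ≥ `green_threshold` (default 0.25) *and*
   its grayscale intensity (luma) ≤ `gray_threshold` (default 0.95) — the
   white background fails both tests. Components smaller than
   `min_object_px` are removed and holes are filled.
2. **Grid partition.** An m × n grid (one genotype per row by convention,
   up to 6 × 6 = 36 plants per dish) splits the analysis rectangle evenly;
   each cell yields one plant mask. Optional region-of-interest polygons
   separate touching rosettes.
3. **Morphometry.** Per plant: pixel area *A*; convex area *C* (pixels in
   the filled convex hull); convex ratio 100·*A*/*C* % — low values flag
   elongated petioles or star-like rosettes. Fresh weight is estimated from
   a linear calibration FW = a + b·*A*ref (areas normalised to the
   reference frame; a well-calibrated setup gives ≈ 1600 px/mg).
4. **Colorimetry.** Per-pixel hue is unwrapped across the red boundary
   (h → h − 1 for h > 0.5), so plant hues span about −0.02…0.24 on one
   continuous axis, then averaged. Linear calibrations map mean hue to
   chlorophyll (µg/pixel, valid 0.2–1.0) and — with negative slope — to
   anthocyanin content.
5. **Growth rates.** From area time series, ln(area) is regressed on time;
   the per-day growth factor is exp(slope) (spreadsheet LOGEST semantics).

Calibration truth comes from the bundled wet-chemistry computations:
chlorophyll a/b/carotenoids from extract absorbances
(Chl a = 13.36·A664.1 − 5.19·A648.6; Chl b = 27.43·A648.6 − 8.12·A664.1;
Car = (1000·A470 − 2.13·Chl a − 97.64·Chl b)/209) and monomeric
anthocyanin by the pH-differential method
(Adiff = (A520−A700)pH1.0 − (A520−A700)pH4.5; mg/L = Adiff × 83.5).

A synthetic plate renderer (`plate_spec()` / `render_plate()`) draws plant
blobs of controlled area, shape and hue on a near-white background with
exact raster-derived ground truth, so the whole pipeline is verifiable
without photographs.

## Worked example

```r
library(phenoplate)

g <- grid_spec(6, 6, row_names = c("Col-0", "Col-0", "hsfa4a", "hsfa4a",
                                   "HSFox", "HSFox"))
spec <- plate_spec(width = 1000, height = 750, grid = g,
                   plants = plant_layout(g, shape = "disk",
                                         area_px = 3000, hue = 0.21))
plate <- render_plate(spec)$image          # or read_plate("plate.jpg")

cal <- read_calibration(system.file("extdata",
        "synthetic_demo_calibration.json", package = "phenoplate"))
rec <- analyze_plate(plate, g, calibration = cal, image_id = "plateA")
dplyr::select(rec, row_name, row, col, area_px, weight_mg,
              convex_ratio_pct, mean_hue, chl_per_px)
#> # A tibble: 36 × 8
#>   row_name   row   col area_px weight_mg convex_ratio_pct mean_hue chl_per_px
#> 1 Col-0        1     1    2997      30.0              100    0.210      0.840
#> 2 Col-0        1     2    2997      30.0              100    0.210      0.840
#> ...
```

One row per grid cell: a 2997-px disk at this 750 × 1000 frame corresponds
to 2997 × 16 ≈ 48k reference-frame pixels, hence 30.0 mg with the demo
slope of 1/1600 mg/px; ratio 100 % means a perfectly convex blob; hue 0.210
sits in the green band and maps to 0.84 µg chlorophyll/pixel with the demo
calibration (both calibrations here are synthetic demos — fit your own with
`calibrate_weight()` / `calibrate_pigment()`).

```r
summarize_plants(rec)                       # n, mean, SD, SE per row name
#>   row_name metric         n n_empty     mean    sd    se
#> 1 Col-0    area_px       12       0 2997.    0.492 0.142
#> ...

growth_rate(data.frame(time = c(0, 3, 6, 9, 12),
                       area = c(500, 905, 1632, 2950, 5320)))
#> <growth_fit> factor 1.2178 per unit time (R^2 1.0000, n 5)
```

Batch processing and export: `run_batch(paths, g, calibration = cal)` then
`export_results(res, "out")` writes `out.csv` plus `out.xml`, an
Excel-compatible workbook with one worksheet per image and a combined
sheet. A command-line wrapper with `analyze`, `batch`, `calibrate`,
`growth` and `synth` verbs is installed at `exec/phenoplate`.

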