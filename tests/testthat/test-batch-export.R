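# Batch orchestration, summaries, and export round trips.

make_demo_plate <- function(seed = 1, grid = grid_spec(3, 2, row_names = c("wt", "mut"))) {
  spec <- plate_spec(width = 300, height = 200, grid = grid,
                     plants = plant_layout(grid, shape = "disk", area_px = 700,
                                           hue = 0.2),
                     seed = seed)
  render_plate(spec)
}

demo_calibration <- function() {
  calibration_set(
    weight = fit_linear(tibble::tibble(x = c(0, 1600), y = c(0, 1)), x, y, "weight"),
    chlorophyll = fit_linear(tibble::tibble(x = c(0.05, 0.25), y = c(0.2, 1.0)), x, y,
                             "chlorophyll"),
    anthocyanin = fit_linear(tibble::tibble(x = c(-0.02, 0.24), y = c(2.0, 0.1)), x, y,
                             "anthocyanin")
  )
}

test_that("analyze_plate returns one populated record per cell with calibration", {
  g <- grid_spec(3, 2, row_names = c("wt", "mut"))
  r <- make_demo_plate(grid = g)
  rec <- analyze_plate(r$image, g, calibration = demo_calibration(), image_id = "p1")
  expect_equal(nrow(rec), 6)
  expect_equal(rec$row_name, rep(c("wt", "mut"), each = 3))
  expect_true(all(rec$area_px > 0))
  expect_true(all(is.finite(rec$weight_mg)))
  expect_true(all(is.finite(rec$chl_per_px)))
  expect_true(all(is.finite(rec$anth_per_px)))
  expect_equal(rec$chl_total, rec$chl_per_px * rec$area_px)
  # weight consistent with the slope at this 300x200 frame
  expect_equal(rec$weight_mg, rec$area_px * (12e6 / (300 * 200)) / 1600,
               tolerance = 1e-9)
})

test_that("an all-white plate yields records with area 0 and empty-cell warnings", {
  plate <- plate_image(array(255L, dim = c(120, 180, 3)))
  rec <- analyze_plate(plate, grid_spec(3, 2), image_id = "blank")
  expect_equal(nrow(rec), 6)
  expect_true(all(rec$area_px == 0))
  expect_true(all(is.na(rec$mean_hue)))
  expect_true(all(grepl("EMPTY_CELL", rec$warnings)))
})

test_that("records match the synthetic ground-truth manifest", {
  g <- grid_spec(4, 4)
  spec <- plate_spec(width = 400, height = 400, grid = g,
                     plants = plant_layout(g, shape = "disk", area_px = 1800))
  r <- render_plate(spec)
  rec <- analyze_plate(r$image, g)
  j <- dplyr::left_join(rec, r$truth, by = c("row", "col"))
  expect_equal(j$area_px, j$true_area_px)
  expect_equal(j$convex_area_px, j$true_convex_area_px)
  expect_equal(j$mean_hue, j$true_mean_hue, tolerance = 1e-12)
})

test_that("batches process in-memory plates and survive corrupt files", {
  g <- grid_spec(3, 2, row_names = c("wt", "mut"))
  dir <- withr::local_tempdir()
  paths <- character(5)
  for (k in 1:4) {
    paths[k] <- file.path(dir, sprintf("plate%02d.png", k))
    write_plate(make_demo_plate(seed = k, grid = g)$image, paths[k])
  }
  paths[5] <- file.path(dir, "corrupt.png")
  writeLines("this is not a png", paths[5])

  res <- run_batch(paths, g)
  expect_equal(res$n_failed, 1)
  expect_equal(sum(res$log$status == "ok"), 4)
  expect_equal(nrow(res$records), 4 * 6)
  expect_match(res$log$message[res$log$status == "failed"], "decode")

  # combined table is sorted by image id / row / col regardless of input order
  res_rev <- run_batch(rev(paths), g)
  expect_equal(res_rev$records, res$records)
})

test_that("export produces a csv twin and a workbook with one sheet per image", {
  g <- grid_spec(3, 2, row_names = c("wt", "mut"))
  plates <- list(make_demo_plate(1, g)$image, make_demo_plate(2, g)$image)
  res <- run_batch(plates, g, calibration = demo_calibration(),
                   ids = c("imgA", "imgB"))
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "out")
  files <- export_results(res, stem)
  expect_true(file.exists(files["csv"]))
  expect_true(file.exists(files["excel"]))

  wb <- read_workbook(files["excel"])
  expect_equal(names(wb), c("imgA", "imgB", "combined"))   # 2 images + combined
  expect_equal(nrow(wb$imgA), 6)                           # 36-cell analogue: n cells
  expect_equal(nrow(wb$combined), 12)
  expect_equal(wb$imgA$area_px, res$per_image$imgA$area_px)
  # numeric cells are numbers, not text
  expect_type(wb$combined$area_px, "double")
  expect_type(wb$combined$weight_mg, "double")

  back <- read_results(files["csv"])
  expect_equal(nrow(back), 12)
  for (col in c("area_px", "weight_mg", "convex_area_px", "convex_ratio_pct",
                "mean_hue", "chl_per_px", "anth_per_px")) {
    expect_equal(back[[col]], res$records[[col]], tolerance = 1e-9, info = col)
  }
  expect_equal(back$warnings, res$records$warnings)

  # long sheet names are truncated to Excel's 31-character limit
  res2 <- run_batch(plates[1], g, ids = paste(rep("x", 40), collapse = ""))
  f2 <- export_results(res2, file.path(dir, "long"))
  expect_equal(nchar(names(read_workbook(f2["excel"]))[1]), 31)
})

test_that("export to an unwritable destination fails before writing anything", {
  res <- run_batch(list(make_demo_plate()$image), grid_spec(3, 2))
  expect_error(export_results(res, "/nonexistent_dir_xyz/out"), "does not exist")
})

test_that("summaries report n, mean, SD, SE per group with empty-cell counts", {
  rec <- tibble::tibble(
    image_id = "i", project = NA, date = NA, label = NA,
    row_name = c("wt", "wt", "mut"), row = c(1, 1, 2), col = c(1, 2, 1),
    area_px = c(10, 20, 0), weight_mg = NA_real_, convex_area_px = c(10, 20, 0),
    convex_ratio_pct = c(100, 100, NA), mean_hue = c(0.2, 0.2, NA),
    chl_per_px = NA_real_, chl_in_range = NA, anth_per_px = NA_real_,
    chl_total = NA_real_, anth_total = NA_real_, warnings = ""
  )
  s <- summarize_plants(rec)
  a_wt <- s[s$row_name == "wt" & s$metric == "area_px", ]
  expect_equal(a_wt$n, 2L)
  expect_equal(a_wt$mean, 15)
  expect_equal(a_wt$sd, 7.071, tolerance = 1e-3)
  expect_equal(a_wt$se, 5.0, tolerance = 1e-3)
  a_mut <- s[s$row_name == "mut" & s$metric == "area_px", ]
  expect_equal(a_mut$n_empty, 1L)
  expect_equal(a_mut$n, 0L)
  # grid (first appearance) ordering, not alphabetical
  expect_equal(unique(s$row_name), c("wt", "mut"))
})

test_that("single-record groups get mean = value and undefined SD", {
  g <- grid_spec(1, 1, row_names = "solo")
  r <- make_demo_plate(grid = g)
  rec <- analyze_plate(r$image, g)
  s <- summarize_plants(rec)
  a <- s[s$metric == "area_px", ]
  expect_equal(a$n, 1L)
  expect_equal(a$mean, rec$area_px)
  expect_true(is.na(a$sd))
})

test_that("run configuration files resolve grid, thresholds and calibration", {
  dir <- withr::local_tempdir()
  cal_path <- file.path(dir, "cal.json")
  write_calibration(demo_calibration(), cal_path)
  cfg_path <- file.path(dir, "run.json")
  jsonlite::write_json(list(
    grid = list(divisor_x = 4, divisor_y = 2, row_names = c("a", "b")),
    segmentation = list(green_threshold = 0.3, gray_threshold = 0.9),
    calibration = "cal.json"
  ), cfg_path, auto_unbox = TRUE)
  setup <- read_run_config(cfg_path)
  expect_equal(setup$grid$ncol, 4)
  expect_equal(setup$grid$row_names, c("a", "b"))
  expect_equal(setup$params$green_threshold, 0.3)
  expect_equal(setup$calibration$weight$slope, 1 / 1600, tolerance = 1e-12)
})
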