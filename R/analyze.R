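# Whole-plate and batch analysis: one record per grid cell per image.

record_columns <- c(
  "image_id", "project", "date", "label", "row_name", "row", "col",
  "area_px", "weight_mg", "convex_area_px", "convex_ratio_pct", "mean_hue",
  "chl_per_px", "chl_in_range", "anth_per_px", "chl_total", "anth_total",
  "warnings"
)

#' Analyze one plate image
#'
#' Runs the full measurement pipeline -- HSV conversion, segmentation,
#' grid partition, shape and color metrics, calibration -- and returns one
#' record per grid cell in row-major order. Empty cells yield records with
#' area 0 and `NA` metrics (warning code `EMPTY_CELL`); per-cell problems
#' accumulate as warning codes and never abort the plate.
#'
#' @param plate a [plate_image()].
#' @param grid a [grid_spec()].
#' @param params a [seg_params()].
#' @param calibration a [calibration_set()] or `NULL` (calibrated columns
#'   stay `NA`).
#' @param image_id identifier used in outputs; defaults to the source file
#'   name (without extension) or `"image"`.
#' @return A tibble with exactly `nrow * ncol` rows and columns `image_id`,
#'   `project`, `date`, `label`, `row_name`, `row`, `col`, `area_px`,
#'   `weight_mg`, `convex_area_px`, `convex_ratio_pct`, `mean_hue`,
#'   `chl_per_px`, `chl_in_range`, `anth_per_px`, `chl_total`,
#'   `anth_total` (derived per-plant totals = per-pixel value x area), and
#'   `warnings` (semicolon-separated codes).
#' @export
analyze_plate <- function(plate, grid, params = seg_params(),
                          calibration = NULL, image_id = NULL) {
  stopifnot(inherits(plate, "plate_image"), inherits(grid, "grid_spec"))
  image_id <- image_id %||% default_image_id(plate)
  hsv <- rgb_to_hsv_image(plate)
  fg <- withCallingHandlers(
    segment_plants(plate, params, hsv),
    phenoplate_no_foreground = function(w) invokeRestart("muffleWarning")
  )
  cells <- partition_grid(fg, grid)
  records <- measure_cells(cells, hsv)
  records <- apply_calibration(records, calibration,
                               image_px_total = plate$height * plate$width)
  records |>
    mutate(
      image_id = image_id, project = plate$project, date = plate$date,
      label = plate$label
    ) |>
    select(all_of(record_columns))
}

default_image_id <- function(plate) {
  if (!is.na(plate$source_path)) {
    sub("\\.[^.]+$", "", basename(plate$source_path))
  } else "image"
}

# shape + color metrics for each cell of a partition_grid() tibble
measure_cells <- function(cells, hsv) {
  met <- purrr::pmap(
    list(cells$mask, cells$x0, cells$y0, cells$x1, cells$y1),
    function(m, x0, y0, x1, y1) {
      cm <- convex_metrics(m)
      mh <- if (any(m)) {
        suppressWarnings(plant_mean_hue(m, hsv, c(x0, y0, x1, y1)))
      } else NA_real_
      c(cm, list(mean_hue = mh))
    }
  )
  cells |>
    mutate(
      area_px = map_int(met, "area_px"),
      convex_area_px = map_int(met, "convex_area_px"),
      convex_ratio_pct = map_dbl(met, "convex_ratio_pct"),
      mean_hue = map_dbl(met, "mean_hue")
    ) |>
    select(-"mask")
}

# add calibrated columns; warnings accumulated per record
apply_calibration <- function(records, calibration, image_px_total) {
  if (!is.null(calibration) && !inherits(calibration, "calibration_set")) {
    abort("calibration must be a calibration_set (or NULL).")
  }
  n <- nrow(records)
  weight_mg <- rep(NA_real_, n)
  chl <- rep(NA_real_, n); chl_ok <- rep(NA, n)
  anth <- rep(NA_real_, n)
  warnings <- records$warnings
  nonempty <- records$area_px > 0

  if (!is.null(calibration$weight)) {
    raw <- calibration$weight$intercept +
      calibration$weight$slope * records$area_px * (12e6 / image_px_total)
    weight_mg <- pmax(raw, 0)
    warnings[nonempty & raw < 0] <- add_warn(warnings[nonempty & raw < 0], "NEGATIVE_CLIPPED")
  }
  if (!is.null(calibration$chlorophyll)) {
    est <- suppressWarnings(
      estimate_chlorophyll(records$mean_hue, calibration$chlorophyll)
    )
    chl <- est$chl_per_px; chl_ok <- est$in_range
    flag <- nonempty & !is.na(chl) & !chl_ok
    warnings[flag] <- add_warn(warnings[flag], "OUT_OF_RANGE_CHL")
  }
  if (!is.null(calibration$anthocyanin)) {
    raw <- calibration$anthocyanin$intercept +
      calibration$anthocyanin$slope * records$mean_hue
    anth <- pmax(raw, 0)
    flag <- nonempty & !is.na(raw) & raw < 0
    warnings[flag] <- add_warn(warnings[flag], "NEGATIVE_CLIPPED")
  }

  records |>
    mutate(
      weight_mg = ifelse(nonempty, weight_mg, NA_real_),
      chl_per_px = ifelse(nonempty, chl, NA_real_),
      chl_in_range = ifelse(nonempty, chl_ok, NA),
      anth_per_px = ifelse(nonempty, anth, NA_real_),
      chl_total = .data$chl_per_px * .data$area_px,
      anth_total = .data$anth_per_px * .data$area_px,
      warnings = warnings
    )
}

#' Batch-analyze a set of plate images
#'
#' Processes images in order with a shared configuration. Per-image
#' failures (unreadable file, grid out of bounds) are logged and skipped;
#' the batch continues. Records are combined into one long table sorted
#' deterministically by image id, row, column, so the combined table does
#' not depend on processing order.
#'
#' @param paths character vector of image files (or a list of
#'   [plate_image()] objects).
#' @param grid a [grid_spec()].
#' @param params a [seg_params()].
#' @param calibration a [calibration_set()] or `NULL`.
#' @param ids optional image ids (default: file names without extension).
#' @return A `plate_results` object: list with `records` (combined
#'   tibble), `per_image` (named list of per-image record tibbles), `log`
#'   (tibble: `image_id`, `path`, `status`, `n_records`, `n_warnings`,
#'   `elapsed_s`, `message`), and `n_failed`.
#' @export
run_batch <- function(paths, grid, params = seg_params(), calibration = NULL,
                      ids = NULL) {
  if (length(paths) < 1) abort("at least one image is required.")
  is_obj <- is.list(paths) && all(vapply(paths, inherits, logical(1), "plate_image"))
  ids <- ids %||% if (is_obj) {
    vapply(paths, default_image_id, character(1))
  } else {
    sub("\\.[^.]+$", "", basename(paths))
  }
  ids <- make.unique(ids, sep = "_")

  per_image <- list()
  log <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    t0 <- Sys.time()
    res <- tryCatch({
      plate <- if (is_obj) paths[[k]] else read_plate(paths[[k]])
      analyze_plate(plate, grid, params, calibration, image_id = ids[k])
    }, error = function(e) e)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      log[[k]] <- tibble(
        image_id = ids[k],
        path = if (is_obj) NA_character_ else as.character(paths[[k]]),
        status = "failed", n_records = 0L, n_warnings = 0L,
        elapsed_s = elapsed, message = conditionMessage(res)
      )
    } else {
      per_image[[ids[k]]] <- res
      log[[k]] <- tibble(
        image_id = ids[k],
        path = if (is_obj) NA_character_ else as.character(paths[[k]]),
        status = "ok", n_records = nrow(res),
        n_warnings = sum(nzchar(res$warnings)),
        elapsed_s = elapsed, message = NA_character_
      )
    }
  }
  log <- bind_rows(log)
  records <- if (length(per_image)) {
    bind_rows(per_image) |> arrange(.data$image_id, .data$row, .data$col)
  } else {
    tibble()
  }
  structure(
    list(records = records, per_image = per_image, log = log,
         n_failed = sum(log$status == "failed")),
    class = "plate_results"
  )
}

#' @export
print.plate_results <- function(x, ...) {
  cat(sprintf("<plate_results> %d image(s), %d record(s), %d failed\n",
              nrow(x$log), nrow(x$records), x$n_failed))
  invisible(x)
}

#' Descriptive statistics per group
#'
#' Per-group n, mean, SD and SE (SD / sqrt(n)) for every numeric metric,
#' the descriptive layer exported for downstream statistics (ANOVA etc. is
#' left to general statistics tools). Empty cells (area 0) are excluded
#' from the statistics; their count is reported per group. Groups follow
#' the order of first appearance (row-name order for a standard grid).
#'
#' @param results a `plate_results` or a record tibble.
#' @param ... grouping columns (tidy evaluation); default `row_name`.
#' @return A long tibble: grouping columns, `metric`, `n`, `n_empty`,
#'   `mean`, `sd`, `se`. `sd`/`se` are `NA` for single-record groups.
#' @export
summarize_plants <- function(results, ...) {
  records <- if (inherits(results, "plate_results")) results$records else as_tibble(results)
  if (nrow(records) == 0) abort("no records to summarize.")
  groups <- rlang::enquos(...)
  if (length(groups) == 0) groups <- rlang::quos(.data$row_name)
  metrics <- intersect(
    c("area_px", "weight_mg", "convex_area_px", "convex_ratio_pct",
      "mean_hue", "chl_per_px", "anth_per_px", "chl_total", "anth_total"),
    names(records)
  )
  out <- records |>
    mutate(.empty = .data$area_px == 0) |>
    tidyr::pivot_longer(all_of(metrics), names_to = "metric", values_to = ".value") |>
    mutate(metric = factor(.data$metric, levels = metrics)) |>
    group_by(!!!groups, .data$metric) |>
    summarise(
      n = sum(!.data$.empty & !is.na(.data$.value)),
      n_empty = sum(.data$.empty),
      mean = mean(.data$.value[!.data$.empty], na.rm = TRUE),
      sd = stats::sd(.data$.value[!.data$.empty], na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(
      mean = ifelse(.data$n > 0, .data$mean, NA_real_),
      se = .data$sd / sqrt(.data$n)
    )
  # groups in first-appearance (grid) order, not alphabetical
  gvars <- intersect(setdiff(names(out), c("metric", "n", "n_empty", "mean", "sd", "se")),
                     names(records))
  if (length(gvars)) {
    first <- unique(do.call(paste, c(records[gvars], sep = "\r")))
    key <- do.call(paste, c(out[gvars], sep = "\r"))
    out <- out[order(match(key, first), as.integer(out$metric)), , drop = FALSE]
  }
  out |> mutate(metric = as.character(.data$metric))
}
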