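# Result export: tidy CSV plus an Excel-compatible workbook with one
# worksheet per image and a combined sheet. The workbook is written as
# SpreadsheetML 2003 XML -- a plain-text, single-file format that Excel and
# LibreOffice open natively -- with numeric cells typed as numbers and
# missing values as empty cells.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

sheet_name <- function(id) {
  id <- gsub("[\\[\\]\\*/:\\\\?]", "_", id)
  substr(id, 1, 31)
}

workbook_cell <- function(v) {
  if (is.na(v)) return("<Cell/>")
  if (is.numeric(v)) {
    sprintf('<Cell><Data ss:Type="Number">%s</Data></Cell>',
            format(v, digits = 15, scientific = FALSE, trim = TRUE))
  } else if (is.logical(v)) {
    sprintf('<Cell><Data ss:Type="Boolean">%d</Data></Cell>', as.integer(v))
  } else {
    sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>', xml_escape(as.character(v)))
  }
}

workbook_sheet <- function(name, df) {
  header <- paste0(vapply(names(df), function(h) {
    sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>', xml_escape(h))
  }, character(1)), collapse = "")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<Row>", paste0(vapply(df[i, ], function(col) workbook_cell(col[[1]]),
                                  character(1)), collapse = ""), "</Row>")
  }, character(1))
  paste0(
    sprintf('<Worksheet ss:Name="%s"><Table>', xml_escape(name)),
    "<Row>", header, "</Row>",
    paste0(rows, collapse = ""),
    "</Table></Worksheet>"
  )
}

#' Write tables to an Excel-compatible workbook
#'
#' @param sheets named list of data frames; names become worksheet names
#'   (truncated to 31 characters, Excel's limit).
#' @param path destination path (`.xml`).
#' @return `path`, invisibly.
#' @export
write_workbook <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1, !is.null(names(sheets)))
  body <- vapply(seq_along(sheets), function(i) {
    workbook_sheet(sheet_name(names(sheets)[i]), as.data.frame(sheets[[i]]))
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<?mso-application progid="Excel.Sheet"?>\n',
    '<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet"',
    ' xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">',
    paste0(body, collapse = ""),
    "</Workbook>\n"
  )
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

#' Read back an Excel-compatible workbook
#'
#' Inverse of [write_workbook()] (used for round-trip validation). Numbers
#' come back numeric, empty cells as `NA`.
#'
#' @param path a workbook written by [write_workbook()].
#' @return Named list of tibbles, one per worksheet.
#' @export
read_workbook <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(ss = "urn:schemas-microsoft-com:office:spreadsheet")
  sheets <- xml2::xml_find_all(doc, ".//ss:Worksheet", ns)
  out <- lapply(sheets, function(ws) {
    rows <- xml2::xml_find_all(ws, ".//ss:Row", ns)
    parsed <- lapply(rows, function(r) {
      cells <- xml2::xml_find_all(r, "./ss:Cell", ns)
      lapply(cells, function(cl) {
        d <- xml2::xml_find_first(cl, "./ss:Data", ns)
        if (inherits(d, "xml_missing")) return(NA)
        type <- xml2::xml_attr(d, "Type")
        txt <- xml2::xml_text(d)
        switch(type,
               Number = as.numeric(txt),
               Boolean = as.logical(as.integer(txt)),
               txt)
      })
    })
    header <- vapply(parsed[[1]], as.character, character(1))
    body <- parsed[-1]
    cols <- lapply(seq_along(header), function(j) {
      vals <- lapply(body, function(r) if (j <= length(r)) r[[j]] else NA)
      types <- vapply(vals, function(v) class(v)[1], character(1))
      if (any(types == "numeric")) {
        vapply(vals, function(v) if (is.na(v)) NA_real_ else as.numeric(v), numeric(1))
      } else if (all(types %in% c("logical", "NA"))) {
        vapply(vals, function(v) if (length(v)) as.logical(v) else NA, logical(1))
      } else {
        vapply(vals, function(v) if (is.na(v)) NA_character_ else as.character(v), character(1))
      }
    })
    names(cols) <- header
    as_tibble(cols)
  })
  names(out) <- vapply(sheets, function(ws) {
    xml2::xml_attr(ws, "Name")
  }, character(1))
  out
}

#' Export batch results
#'
#' Writes the combined record table as a tidy CSV (`<stem>.csv`) and/or an
#' Excel-compatible workbook (`<stem>.xml`) with one worksheet per image
#' (sheet name = image id, truncated to 31 characters) plus a `"combined"`
#' sheet. The destination directory is checked before anything is written,
#' so an unwritable path leaves no partial files.
#'
#' @param results a `plate_results` from [run_batch()] (or a record tibble,
#'   exported as a single sheet).
#' @param stem output path stem (no extension).
#' @param formats subset of `c("csv", "excel")`.
#' @return Named character vector of the files written, invisibly.
#' @export
export_results <- function(results, stem, formats = c("csv", "excel")) {
  formats <- match.arg(formats, c("csv", "excel"), several.ok = TRUE)
  dir <- dirname(stem)
  if (!dir.exists(dir)) abort(sprintf("output directory does not exist: '%s'", dir))
  if (file.access(dir, 2) != 0) abort(sprintf("output directory is not writable: '%s'", dir))

  if (inherits(results, "plate_results")) {
    combined <- results$records
    per_image <- results$per_image
  } else {
    combined <- as_tibble(results)
    per_image <- list()
  }
  written <- character(0)
  if ("csv" %in% formats) {
    csv_path <- paste0(stem, ".csv")
    readr::write_csv(combined, csv_path, na = "")
    written["csv"] <- csv_path
  }
  if ("excel" %in% formats) {
    wb_path <- paste0(stem, ".xml")
    sheets <- c(per_image, list(combined = combined))
    write_workbook(sheets, wb_path)
    written["excel"] <- wb_path
  }
  invisible(written)
}

#' Read back an exported record CSV
#'
#' @param path a CSV written by [export_results()].
#' @return A record tibble with the exported column types.
#' @export
read_results <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(
                    image_id = "c", project = "c", date = "c", label = "c",
                    row_name = "c", warnings = "c", .default = readr::col_guess()
                  )) |>
    mutate(warnings = ifelse(is.na(.data$warnings), "", .data$warnings))
}

#' Read a run configuration file
#'
#' JSON with keys `grid` (`divisor_x`, `divisor_y`, `row_names`,
#' `analysis_rect`), `segmentation` (`green_threshold`, `gray_threshold`,
#' `min_object_px`) and optional `calibration` (path to a
#' [write_calibration()] JSON). All keys optional; defaults fill the gaps.
#'
#' @param path JSON config path.
#' @return List with `grid` ([grid_spec()]), `params` ([seg_params()]),
#'   `calibration` ([calibration_set()] or `NULL`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file does not exist: '%s'", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- cfg$grid %||% list()
  grid <- grid_spec(
    ncol = g$divisor_x %||% 6, nrow = g$divisor_y %||% 6,
    row_names = g$row_names,
    analysis_rect = g$analysis_rect
  )
  s <- cfg$segmentation %||% list()
  params <- seg_params(
    green_threshold = s$green_threshold %||% 0.25,
    gray_threshold = s$gray_threshold %||% 0.95,
    min_object_px = s$min_object_px
  )
  calibration <- if (!is.null(cfg$calibration)) {
    cal_path <- cfg$calibration
    if (!file.exists(cal_path)) {
      cal_path2 <- file.path(dirname(path), cal_path)
      if (file.exists(cal_path2)) cal_path <- cal_path2
    }
    read_calibration(cal_path)
  }
  list(grid = grid, params = params, calibration = calibration)
}

#' Write a segmentation preview overlay
#'
#' Writes the plate image with segmented plant pixels tinted magenta so an
#' operator can eyeball threshold quality before a batch run.
#'
#' @param plate a [plate_image()].
#' @param mask logical mask from [segment_plants()].
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_overlay <- function(plate, mask, path) {
  px <- plate$pixels
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  r[mask] <- pmin(255, 0.5 * r[mask] + 128)
  g[mask] <- 0.5 * g[mask]
  b[mask] <- pmin(255, 0.5 * b[mask] + 128)
  out <- array(c(r, g, b), dim = dim(px))
  write_plate(plate_image(out), path)
}
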