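#' Grid specification for a plate
#'
#' Plants are arranged on the plate in an `nrow x ncol` matrix, conventionally
#' one genotype per row. The analysis rectangle (0-based, half-open pixel
#' bounds `(x0, y0, x1, y1)`) is split into an evenly distributed grid;
#' when the rectangle does not divide exactly, the first cells of each axis
#' absorb the remainder pixels.
#'
#' @param ncol,nrow number of grid columns / rows (>= 1).
#' @param row_names optional character vector of `nrow` labels (genotypes);
#'   defaults to `"row1"`, `"row2"`, ...
#' @param analysis_rect optional `(x0, y0, x1, y1)`; `NULL` means the full
#'   image (resolved when the grid is applied).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(ncol, nrow, row_names = NULL, analysis_rect = NULL) {
  if (!is_number(ncol) || ncol < 1 || !is_number(nrow) || nrow < 1) {
    abort("ncol and nrow must be positive integers.")
  }
  ncol <- as.integer(ncol); nrow <- as.integer(nrow)
  row_names <- row_names %||% paste0("row", seq_len(nrow))
  if (length(row_names) != nrow) {
    abort(sprintf("row_names has %d entries but the grid has %d rows.",
                  length(row_names), nrow))
  }
  structure(
    list(ncol = ncol, nrow = nrow, row_names = as.character(row_names),
         analysis_rect = if (is.null(analysis_rect)) NULL else as.integer(analysis_rect)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols (%s)\n", x$nrow, x$ncol,
              paste(x$row_names, collapse = ", ")))
  if (!is.null(x$analysis_rect)) {
    cat("  analysis_rect:", paste(x$analysis_rect, collapse = ", "), "\n")
  }
  invisible(x)
}

grid_cell_rects <- function(grid, width, height) {
  rect <- grid$analysis_rect %||% c(0L, 0L, width, height)
  rect <- validate_rect(rect, width, height)
  xs <- split_interval(rect[1], rect[3], grid$ncol)
  ys <- split_interval(rect[2], rect[4], grid$nrow)
  if (any(xs[, 2] - xs[, 1] < 1) || any(ys[, 2] - ys[, 1] < 1)) {
    abort("analysis_rect is too small for the requested grid (empty cells).")
  }
  list(xs = xs, ys = ys, rect = rect)
}

#' Partition a foreground mask into per-plant grid cells
#'
#' Restricts the segmented foreground to each grid cell, yielding one plant
#' mask per cell in row-major order (row 1 left-to-right first). Plants
#' crossing a cell boundary are truncated at the boundary; cells whose
#' foreground touches a cell edge are flagged with the `EDGE_TOUCH` warning
#' code so the operator can re-arrange or dissect plants.
#'
#' @param mask logical `H x W` foreground matrix (from [segment_plants()]).
#' @param grid a [grid_spec()].
#' @return A tibble with one row per cell: `row`, `col`, `row_name`,
#'   `x0`, `y0`, `x1`, `y1` (cell bounds, 0-based half-open), `mask`
#'   (list-column of cell-local logical matrices) and `warnings`
#'   (semicolon-separated codes).
#' @export
partition_grid <- function(mask, grid) {
  stopifnot(is.matrix(mask), is.logical(mask), inherits(grid, "grid_spec"))
  g <- grid_cell_rects(grid, ncol(mask), nrow(mask))
  cells <- tidyr::expand_grid(row = seq_len(grid$nrow), col = seq_len(grid$ncol))
  out <- purrr::pmap(cells, function(row, col) {
    xr <- g$xs[col, ]; yr <- g$ys[row, ]
    sub <- mask[(yr[1] + 1):yr[2], (xr[1] + 1):xr[2], drop = FALSE]
    edge <- any(sub[1, ]) || any(sub[nrow(sub), ]) ||
      any(sub[, 1]) || any(sub[, ncol(sub)])
    list(
      x0 = xr[1], y0 = yr[1], x1 = xr[2], y1 = yr[2],
      mask = sub,
      warnings = join_warn(c(
        if (!any(sub)) "EMPTY_CELL",
        if (edge && any(sub)) "EDGE_TOUCH"
      ))
    )
  })
  tibble(
    row = cells$row,
    col = cells$col,
    row_name = grid$row_names[cells$row],
    x0 = map_int(out, ~ as.integer(.x$x0)),
    y0 = map_int(out, ~ as.integer(.x$y0)),
    x1 = map_int(out, ~ as.integer(.x$x1)),
    y1 = map_int(out, ~ as.integer(.x$y1)),
    mask = map(out, "mask"),
    warnings = map_chr(out, "warnings")
  )
}

#' Clip one plant mask with a region-of-interest polygon
#'
#' Replaces a cell's mask by its intersection with the rasterized polygon
#' interior (pixel centers inside or on the boundary), e.g. to separate a
#' rosette from a neighbour leaf reaching into the cell. The polygon is
#' given in full-image pixel coordinates (0-based, `x` right, `y` down);
#' the cell bounds are unchanged.
#'
#' @param cells the tibble from [partition_grid()].
#' @param row,col cell index (1-based).
#' @param polygon numeric matrix or data frame with columns `x`, `y` and at
#'   least 3 vertices of non-zero area.
#' @return `cells` with the selected mask clipped.
#' @export
refine_roi <- function(cells, row, col, polygon) {
  polygon <- as.matrix(as.data.frame(polygon))
  if (ncol(polygon) < 2 || nrow(polygon) < 3) {
    abort("polygon must have at least 3 (x, y) vertices.")
  }
  px <- polygon[, 1]; py <- polygon[, 2]
  if (abs(pracma::polyarea(px, py)) < 0.5) {
    abort("polygon is degenerate (zero area).")
  }
  i <- which(cells$row == row & cells$col == col)
  if (length(i) != 1) abort(sprintf("no cell at row %s, col %s.", row, col))
  m <- cells$mask[[i]]
  # pixel centers of the cell in global 0-based coordinates
  gx <- cells$x0[i] + (seq_len(ncol(m)) - 1L)
  gy <- cells$y0[i] + (seq_len(nrow(m)) - 1L)
  pts <- expand.grid(y = gy, x = gx)
  inside <- pracma::inpolygon(pts$x, pts$y, px, py, boundary = TRUE)
  clip <- matrix(inside, nrow(m), ncol(m))
  cells$mask[[i]] <- m & clip
  if (!any(cells$mask[[i]]) && !grepl("EMPTY_CELL", cells$warnings[i])) {
    cells$warnings[i] <- add_warn(cells$warnings[i], "EMPTY_CELL")
  }
  cells
}
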