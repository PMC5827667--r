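# Synthetic plate renderer: controlled plant blobs on a near-white
# background with exact raster-derived ground truth, so segmentation,
# morphometry and colorimetry are testable without photographs.

#' Lay out identical synthetic plants on a grid
#'
#' Builds the per-cell plant table for [plate_spec()]. Arguments of length
#' one are recycled across all cells; vectors must match the cell count
#' (row-major order).
#'
#' @param grid a [grid_spec()].
#' @param shape one of `"disk"`, `"square"`, `"plus"`, `"star"`, `"absent"`.
#' @param area_px target pixel area per plant (the rendered raster area is
#'   exact for squares and within rasterization tolerance otherwise).
#' @param hue unwrapped hue in `[-0.5, 0.5)` of the plant color.
#' @param saturation,value HSV saturation and value of the plant color.
#' @return Tibble with columns `row`, `col`, `shape`, `area_px`, `hue`,
#'   `saturation`, `value`.
#' @export
plant_layout <- function(grid, shape = "disk", area_px = 3000, hue = 0.21,
                         saturation = 0.85, value = 0.55) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- tidyr::expand_grid(row = seq_len(grid$nrow), col = seq_len(grid$ncol))
  n <- nrow(cells)
  rec <- function(x, what) {
    if (length(x) == 1) rep(x, n)
    else if (length(x) == n) x
    else abort(sprintf("%s must have length 1 or %d.", what, n))
  }
  tibble(
    row = cells$row, col = cells$col,
    shape = rec(shape, "shape"), area_px = rec(area_px, "area_px"),
    hue = rec(hue, "hue"), saturation = rec(saturation, "saturation"),
    value = rec(value, "value")
  )
}

#' Synthetic plate specification
#'
#' Describes a renderable plate: image size, grid, per-cell plants, a
#' near-white background, optional per-channel Gaussian noise and optional
#' radial vignetting (both off by default), and a seed making rendering
#' deterministic. The default frame is 750 x 1000 px (1/16 of the
#' 3000 x 4000 reference acquisition frame) to keep validation fast.
#'
#' @param width,height image size in pixels.
#' @param grid a [grid_spec()].
#' @param plants per-cell plant table from [plant_layout()]; rows may be
#'   omitted (missing cells are background).
#' @param background background RGB, 0--255; default `c(252, 252, 252)`
#'   (saturation 0, luma 0.988 -- near-white as on a transilluminator).
#' @param noise_sd per-channel Gaussian noise SD on the 0--1 scale
#'   (0 = off; 2/255 is a realistic sensor level).
#' @param vignette logical; apply a mild radial darkening (10% at corners).
#' @param seed integer seed for the noise generator.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(width = 1000, height = 750, grid = grid_spec(6, 6),
                       plants = plant_layout(grid), background = c(252, 252, 252),
                       noise_sd = 0, vignette = FALSE, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  plants <- as_tibble(plants)
  need <- c("row", "col", "shape", "area_px", "hue", "saturation", "value")
  if (!all(need %in% names(plants))) {
    abort(paste0("plants must have columns: ", paste(need, collapse = ", ")))
  }
  bad_shape <- setdiff(unique(plants$shape), c("disk", "square", "plus", "star", "absent"))
  if (length(bad_shape)) {
    abort(paste0("unknown plant shape(s): ", paste(bad_shape, collapse = ", ")))
  }
  if (any(plants$hue < -0.5 | plants$hue >= 0.5)) {
    abort("plant hue must lie in [-0.5, 0.5).")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height), grid = grid,
         plants = plants, background = as.numeric(background),
         noise_sd = noise_sd, vignette = isTRUE(vignette), seed = as.integer(seed)),
    class = "plate_spec"
  )
}

# Local raster of one plant shape, centered in a cw x ch cell.
# Returns a logical ch x cw matrix. Errors if the shape cannot fit.
shape_raster <- function(shape, area_px, cw, ch) {
  if (shape == "absent" || area_px <= 0) return(matrix(FALSE, ch, cw))
  cx <- (cw + 1) / 2; cy <- (ch + 1) / 2
  xs <- matrix(rep(seq_len(cw), each = ch), ch, cw)
  ys <- matrix(rep(seq_len(ch), times = cw), ch, cw)
  m <- switch(shape,
    disk = {
      r <- sqrt(area_px / pi)
      if (2 * r > min(cw, ch)) abort_shape(shape, area_px, cw, ch)
      (xs - cx)^2 + (ys - cy)^2 <= r^2
    },
    square = {
      s <- max(1L, round(sqrt(area_px)))
      if (s > min(cw, ch)) abort_shape(shape, area_px, cw, ch)
      x0 <- floor(cx - s / 2)
      y0 <- floor(cy - s / 2)
      xs > x0 & xs <= x0 + s & ys > y0 & ys <= y0 + s
    },
    plus = {
      # two orthogonal bars, length 5w, width w: area = 2*(5w)w - w^2 = 9w^2
      w <- max(2L, round(sqrt(area_px / 9)))
      L <- 5L * w
      if (L > min(cw, ch)) abort_shape(shape, area_px, cw, ch)
      hx <- abs(xs - cx); hy <- abs(ys - cy)
      (hx <= L / 2 & hy <= w / 2) | (hy <= L / 2 & hx <= w / 2)
    },
    star = {
      # 5-pointed star polygon, inner/outer radius ratio 0.45,
      # outer radius solved from the analytic polygon area
      ratio <- 0.45
      ang <- pi / 2 + (0:9) * pi / 5
      rad1 <- c(1, ratio)[rep(1:2, 5)]
      unit_area <- abs(pracma::polyarea(rad1 * cos(ang), rad1 * sin(ang)))
      R <- sqrt(area_px / unit_area)
      if (2 * R > min(cw, ch)) abort_shape(shape, area_px, cw, ch)
      vx <- cx + R * rad1 * cos(ang)
      vy <- cy + R * rad1 * sin(ang)
      matrix(pracma::inpolygon(as.vector(xs), as.vector(ys), vx, vy, boundary = TRUE),
             ch, cw)
    },
    abort(sprintf("unknown shape '%s'", shape))
  )
  m
}

abort_shape <- function(shape, area_px, cw, ch) {
  abort(sprintf("%s of target area %g px does not fit in a %d x %d cell.",
                shape, area_px, cw, ch))
}

# Largest target area of `shape` fitting a cw x ch cell with 1 px margin.
max_shape_area <- function(shape, cw, ch) {
  d <- min(cw, ch) - 2
  if (d < 1) return(0)
  switch(shape,
    disk = pi * (d / 2)^2,
    square = d^2,
    plus = 9 * (d / 5)^2,
    star = {
      ratio <- 0.45
      ang <- pi / 2 + (0:9) * pi / 5
      rad1 <- c(1, ratio)[rep(1:2, 5)]
      abs(pracma::polyarea(rad1 * cos(ang), rad1 * sin(ang))) * (d / 2)^2
    },
    absent = Inf
  )
}

#' Render a synthetic plate
#'
#' Produces the plate image and a ground-truth table computed from the
#' rendered raster itself (not the analytic shapes), so downstream
#' measurements can be compared exactly. Plant colors are the 8-bit
#' quantization of the requested HSV color; the true mean hue is the
#' unwrapped hue of that quantized color. Rendering is deterministic given
#' the spec's seed.
#'
#' @param spec a [plate_spec()].
#' @return A list with `image` (a [plate_image()]) and `truth` (tibble:
#'   `row`, `col`, `shape`, `true_area_px`, `true_convex_area_px`,
#'   `true_convex_ratio_pct`, `true_mean_hue`).
#' @export
render_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  h <- spec$height; w <- spec$width
  px <- array(0, dim = c(h, w, 3))
  for (c in 1:3) px[, , c] <- spec$background[c]

  g <- grid_cell_rects(spec$grid, w, h)
  truth <- vector("list", nrow(spec$plants))
  for (i in seq_len(nrow(spec$plants))) {
    p <- spec$plants[i, ]
    xr <- g$xs[p$col, ]; yr <- g$ys[p$row, ]
    cw <- xr[2] - xr[1]; ch <- yr[2] - yr[1]
    m <- shape_raster(p$shape, p$area_px, cw, ch)
    raw_hue <- p$hue %% 1
    col8 <- round(255 * grDevices::col2rgb(
      grDevices::hsv(raw_hue, p$saturation, p$value)) / 255)
    if (any(m)) {
      rows <- (yr[1] + 1):yr[2]; cols <- (xr[1] + 1):xr[2]
      for (c in 1:3) {
        sub <- px[rows, cols, c]
        sub[m] <- col8[c]
        px[rows, cols, c] <- sub
      }
      # truth from the rendered raster and the quantized color
      cm <- convex_metrics(m)
      qhsv <- grDevices::rgb2hsv(col8, maxColorValue = 255)
      truth[[i]] <- tibble(
        row = p$row, col = p$col, shape = p$shape,
        true_area_px = cm$area_px,
        true_convex_area_px = cm$convex_area_px,
        true_convex_ratio_pct = cm$convex_ratio_pct,
        true_mean_hue = unname(unwrap_hue(qhsv[1, 1] %% 1))
      )
    } else {
      truth[[i]] <- tibble(
        row = p$row, col = p$col, shape = p$shape,
        true_area_px = 0L, true_convex_area_px = 0L,
        true_convex_ratio_pct = NA_real_, true_mean_hue = NA_real_
      )
    }
  }
  truth <- bind_rows(truth) |> arrange(.data$row, .data$col)

  if (spec$vignette) {
    cx <- (w + 1) / 2; cy <- (h + 1) / 2
    rmax2 <- (cx - 1)^2 + (cy - 1)^2
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)
    fac <- 1 - 0.1 * ((xs - cx)^2 + (ys - cy)^2) / rmax2
    for (c in 1:3) px[, , c] <- px[, , c] * fac
  }
  if (spec$noise_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(spec$seed)
    px <- px + array(rnorm(length(px), 0, spec$noise_sd * 255), dim = dim(px))
  }
  px <- round(pmin(pmax(px, 0), 255))

  list(image = plate_image(px), truth = truth)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Render an exponentially growing time series of plates
#'
#' Scales every plant's target area by `growth_factor^day` and re-renders
#' the plate for each day, emulating the repeated photography of a growth
#' assay. Areas that would overflow their cell are capped at the largest
#' fitting size, with a warning (real assays stop measuring once rosettes
#' meet, typically around two weeks).
#'
#' @param base a [plate_spec()] giving the day-0 plate.
#' @param growth_factor per-day growth factor (> 0), e.g. 2.0 for doubling.
#' @param days numeric vector of days to render.
#' @return A named list (`"day<d>"`) of [render_plate()] results.
#' @export
render_timeseries <- function(base, growth_factor, days) {
  stopifnot(inherits(base, "plate_spec"), growth_factor > 0)
  g <- grid_cell_rects(base$grid, base$width, base$height)
  out <- vector("list", length(days))
  capped_any <- FALSE
  for (k in seq_along(days)) {
    d <- days[k]
    sp <- base
    sp$seed <- base$seed + k - 1L
    target <- base$plants$area_px * growth_factor^d
    cap <- purrr::map2_dbl(base$plants$shape, seq_len(nrow(base$plants)), function(s, i) {
      xr <- g$xs[base$plants$col[i], ]; yr <- g$ys[base$plants$row[i], ]
      max_shape_area(s, xr[2] - xr[1], yr[2] - yr[1])
    })
    if (any(target > cap)) capped_any <- TRUE
    sp$plants$area_px <- pmin(target, cap)
    out[[k]] <- render_plate(sp)
  }
  if (capped_any) {
    warn("some plants reached their cell capacity and were size-capped (SHAPE_CAPPED).",
         class = "phenoplate_shape_capped")
  }
  names(out) <- paste0("day", days)
  out
}
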