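# Size and shape descriptors: pixel area, filled convex hull, convex ratio,
# and calibrated fresh weight.

#' Pixel area of a plant mask
#'
#' @param mask logical matrix (one cell's mask).
#' @return Integer count of `TRUE` pixels (0 for an empty mask).
#' @export
pixel_area <- function(mask) {
  stopifnot(is.logical(mask))
  as.integer(sum(mask))
}

# Membership of lattice points in the convex hull of `pts` (n x 2, columns
# x,y). Pixel-fill convention: a pixel belongs to the hull when its center
# lies inside or on the hull polygon, so the hull of a filled rectangle is
# exactly the rectangle. Collinear masks degenerate to lattice points on the
# extreme segment.
hull_pixel_count <- function(pts) {
  n <- nrow(pts)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  ux <- unique(pts[, 1]); uy <- unique(pts[, 2])
  # collinearity: all cross products with the first edge vanish
  v <- cbind(pts[, 1] - pts[1, 1], pts[, 2] - pts[1, 2])
  ref <- v[which.max(abs(v[, 1]) + abs(v[, 2])), ]
  collinear <- all(abs(v[, 1] * ref[2] - v[, 2] * ref[1]) < 1e-9)
  if (collinear) {
    # extreme points along the line; lattice points on the closed segment
    t <- v %*% ref
    a <- pts[which.min(t), ]; b <- pts[which.max(t), ]
    return(as.integer(gcd2(b[1] - a[1], b[2] - a[2]) + 1L))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  poly <- pts[h, , drop = FALSE]
  # orient so interior points satisfy cross >= 0 (positive shoelace sum)
  a2 <- sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
              c(poly[-1, 1], poly[1, 1]) * poly[, 2])
  if (a2 < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
  xs <- seq(min(ux), max(ux))
  ys <- seq(min(uy), max(uy))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- rep(TRUE, length(gx))
  k <- nrow(poly)
  for (e in seq_len(k)) {
    p <- poly[e, ]; q <- poly[if (e == k) 1 else e + 1, ]
    cross <- (q[1] - p[1]) * (gy - p[2]) - (q[2] - p[2]) * (gx - p[1])
    inside <- inside & (cross >= -1e-9)
  }
  as.integer(sum(inside))
}

#' Convex-hull shape metrics
#'
#' Computes the pixel count of the filled convex hull of a plant mask and
#' the convex ratio, `100 * area / convex_area` (%). A compact round
#' rosette has ratio near 100; elongated petioles or a star-like outline
#' leave empty wedges inside the hull and push the ratio down, which is the
#' shape signal used to separate e.g. phytochrome-B mutants from wild type.
#'
#' @param mask logical matrix (one cell's mask).
#' @return A list with `area_px`, `convex_area_px`, `convex_ratio_pct`
#'   (`NA` for an empty mask).
#' @export
convex_metrics <- function(mask) {
  area <- pixel_area(mask)
  if (area == 0) {
    return(list(area_px = 0L, convex_area_px = 0L, convex_ratio_pct = NA_real_))
  }
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  hull <- hull_pixel_count(pts)
  list(
    area_px = area,
    convex_area_px = hull,
    convex_ratio_pct = 100 * area / hull
  )
}

#' Estimate fresh weight from pixel area
#'
#' Applies a fitted area-to-fresh-weight calibration. Areas are first
#' normalised to the 3000 x 4000 reference frame (12e6 px) by scaling
#' linearly with total image pixel count, so a calibration made at the
#' reference resolution transfers to other image sizes. A well-calibrated
#' setup gives roughly 1 mg fresh weight per 1600 reference-frame pixels.
#' Negative predictions are clipped to 0.
#'
#' @param area_px pixel area(s) of the plant mask.
#' @param model a `cal_model` from [calibrate_weight()] or [fit_linear()].
#' @param image_px_total total pixel count of the source image (default the
#'   reference frame, 12e6).
#' @return Fresh weight(s) in mg.
#' @export
estimate_weight <- function(area_px, model, image_px_total = 12e6) {
  if (is.null(model)) {
    abort("no weight calibration model supplied; fit one with calibrate_weight().")
  }
  stopifnot(inherits(model, "cal_model"), image_px_total > 0)
  area_scaled <- area_px * (12e6 / image_px_total)
  fw <- model$intercept + model$slope * area_scaled
  neg <- !is.na(fw) & fw < 0
  if (any(neg)) {
    warn(sprintf("%d negative weight prediction(s) clipped to 0 mg.", sum(neg)),
         class = "phenoplate_negative_clipped")
    fw[neg] <- 0
  }
  fw
}
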