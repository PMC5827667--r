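#' Segmentation parameters
#'
#' The two thresholds mirror the "Green" and "Gray" sliders of interactive
#' plate analysis: a pixel is plant foreground when its HSV saturation is at
#' least `green_threshold` AND its grayscale intensity (luma) is at most
#' `gray_threshold`. The white background has near-zero saturation and high
#' luma, so both tests remove it. Connected components smaller than
#' `min_object_px` are discarded as noise and holes inside the remaining
#' objects are filled, which replaces the interactive clean-up of a GUI with
#' a deterministic batch rule.
#'
#' @param green_threshold minimum saturation in `[0, 1]`. Default 0.25.
#' @param gray_threshold maximum luma in `[0, 1]`, with
#'   luma = (0.299 R + 0.587 G + 0.114 B) / 255. Default 0.95.
#' @param min_object_px minimum connected-component size in pixels, or `NULL`
#'   (default) to scale the reference value of 50 px at 3000 x 4000 by the
#'   actual image area.
#' @return A `seg_params` list.
#' @export
seg_params <- function(green_threshold = 0.25, gray_threshold = 0.95,
                       min_object_px = NULL) {
  if (!is_number(green_threshold) || green_threshold < 0 || green_threshold > 1) {
    abort("green_threshold must be a single number in [0, 1].")
  }
  if (!is_number(gray_threshold) || gray_threshold < 0 || gray_threshold > 1) {
    abort("gray_threshold must be a single number in [0, 1].")
  }
  if (!is.null(min_object_px)) {
    if (!is_number(min_object_px) || min_object_px < 1) {
      abort("min_object_px must be a positive integer (or NULL for auto).")
    }
    min_object_px <- as.integer(min_object_px)
  }
  structure(
    list(
      green_threshold = green_threshold,
      gray_threshold = gray_threshold,
      min_object_px = min_object_px
    ),
    class = "seg_params"
  )
}

resolve_min_object_px <- function(params, n_px) {
  params$min_object_px %||% max(1L, as.integer(round(50 * n_px / 12e6)))
}

#' Segment plant foreground
#'
#' Applies the two-threshold rule of [seg_params()], removes connected
#' components below the minimum object size (8-connectivity), and fills
#' holes (e.g. specular highlights) inside the surviving objects.
#'
#' @param plate a [plate_image()].
#' @param params a [seg_params()].
#' @param hsv optional precomputed [rgb_to_hsv_image()] result (recomputed
#'   when `NULL`).
#' @return Logical `H x W` matrix, `TRUE` = plant pixel. An all-background
#'   image returns an empty mask with a warning.
#' @export
segment_plants <- function(plate, params = seg_params(), hsv = NULL) {
  stopifnot(inherits(plate, "plate_image"))
  hsv <- hsv %||% rgb_to_hsv_image(plate)
  if (!identical(dim(hsv$saturation), dim(plate$pixels)[1:2])) {
    abort("hsv image dimensions do not match the plate image.")
  }
  fg <- hsv$saturation >= params$green_threshold &
    plate_luma(plate) <= params$gray_threshold

  if (any(fg)) {
    min_px <- resolve_min_object_px(params, length(fg))
    if (min_px > 1) {
      lab <- EBImage::bwlabel(EBImage::Image(t(fg) * 1))
      labm <- t(EBImage::imageData(lab))
      sizes <- tabulate(labm)
      keep <- which(sizes >= min_px)
      fg <- matrix(labm %in% keep, nrow(fg), ncol(fg))
    }
    if (any(fg)) {
      filled <- EBImage::fillHull(EBImage::Image(t(fg) * 1))
      fg <- t(EBImage::imageData(filled)) > 0
    }
  }
  if (!any(fg)) {
    warn("segmentation found no plant foreground (empty mask returned).",
         class = "phenoplate_no_foreground")
  }
  fg
}
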