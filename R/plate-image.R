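#' Plate image container
#'
#' An 8-bit RGB raster with acquisition metadata. Pixels are stored as an
#' integer array `[row, column, channel]` with values in 0--255, row 1 at the
#' top of the image. The reference acquisition frame is 3000 x 4000 pixels;
#' any size is accepted and area-dependent quantities are normalised to the
#' reference frame downstream.
#'
#' @param pixels numeric array `H x W x 3` with values in 0--255.
#' @param source_path optional path the image was decoded from.
#' @param project,date,label optional free-text acquisition metadata.
#' @return A `plate_image` object: list with elements `pixels`, `width`,
#'   `height`, `source_path`, `project`, `date`, `label`.
#' @export
plate_image <- function(pixels, source_path = NA_character_, project = NULL,
                        date = NULL, label = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("pixels must be an H x W x 3 array of 8-bit RGB values.")
  }
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) {
    abort("image must have at least one row and one column of pixels.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("pixel channel values must lie in [0, 255].")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(
      pixels = pixels,
      height = dim(pixels)[1],
      width = dim(pixels)[2],
      source_path = source_path,
      project = project %||% NA_character_,
      date = date %||% NA_character_,
      label = label %||% NA_character_
    ),
    class = "plate_image"
  )
}

#' Read a plate photograph
#'
#' Decodes an 8-bit RGB JPEG or PNG exactly as stored (an alpha channel, if
#' present, is dropped). Grayscale or otherwise non-RGB images are rejected:
#' segmentation and hue extraction require three color channels.
#'
#' @param path path to a JPEG or PNG file.
#' @inheritParams plate_image
#' @return A [plate_image()].
#' @export
read_plate <- function(path, project = NULL, date = NULL, label = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("image file does not exist: '%s'", path))
  }
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) abort(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)))
  )
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) != 3 || dim(dat)[3] < 3) {
    abort(sprintf("'%s' is not an RGB image (grayscale and indexed images are not supported).", path))
  }
  dat <- dat[, , 1:3, drop = FALSE]              # drop alpha if present
  px <- aperm(dat, c(2, 1, 3))                   # EBImage stores x,y,c
  px <- array(as.integer(round(px * 255)), dim = dim(px))
  plate_image(px, source_path = path, project = project, date = date, label = label)
}

#' Write a plate image to a lossless PNG
#'
#' @param plate a [plate_image()].
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "plate_image"))
  img <- EBImage::Image(aperm(plate$pixels / 255, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf(
    "<plate_image> %d x %d px (8-bit RGB)\n", x$height, x$width
  ))
  meta <- c(project = x$project, date = x$date, label = x$label)
  meta <- meta[!is.na(meta)]
  if (length(meta)) cat(paste0("  ", names(meta), ": ", meta, collapse = "\n"), "\n")
  if (!is.na(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' Convert a plate image to HSV
#'
#' Standard hexcone RGB-to-HSV transform. Hue is in `[0, 1)` (0 = red,
#' 1/3 = green, 2/3 = blue), saturation and value in `[0, 1]`. Achromatic
#' pixels get hue 0 by convention.
#'
#' @param plate a [plate_image()].
#' @return An `hsv_image`: list of `hue`, `saturation`, `value` matrices of
#'   the same height/width as the input.
#' @export
rgb_to_hsv_image <- function(plate) {
  stopifnot(inherits(plate, "plate_image"))
  px <- plate$pixels
  m <- rbind(
    as.vector(px[, , 1]),
    as.vector(px[, , 2]),
    as.vector(px[, , 3])
  )
  hsvm <- grDevices::rgb2hsv(m, maxColorValue = 255)
  h <- plate$height; w <- plate$width
  structure(
    list(
      hue = matrix(hsvm[1, ] %% 1, h, w),
      saturation = matrix(hsvm[2, ], h, w),
      value = matrix(hsvm[3, ], h, w)
    ),
    class = "hsv_image"
  )
}

#' @export
print.hsv_image <- function(x, ...) {
  cat(sprintf("<hsv_image> %d x %d px\n", nrow(x$hue), ncol(x$hue)))
  invisible(x)
}

#' Unwrap hue across the red boundary
#'
#' Hues just below 1 (magenta-reds) are mapped to small negative values
#' (`h - 1` for `h > 0.5`), so that the green-to-red color shift caused by
#' anthocyanin accumulation is monotone on a single linear axis. Observed
#' plant hues then span roughly -0.02 to 0.24, matching the band over which
#' the pigment calibrations are linear.
#'
#' @param h numeric vector of raw hues in `[0, 1)`.
#' @return Unwrapped hues in `[-0.5, 0.5)`.
#' @export
unwrap_hue <- function(h) {
  ifelse(h > 0.5, h - 1, h)
}

# luma in [0,1] used by the "gray" segmentation threshold
plate_luma <- function(plate) {
  px <- plate$pixels
  (0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]) / 255
}
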