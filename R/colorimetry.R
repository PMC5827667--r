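# Color summaries and hue-based pigment estimation.

#' Mean unwrapped hue of a plant
#'
#' Per-pixel hues under the mask are unwrapped across the red boundary
#' ([unwrap_hue()]) and averaged arithmetically. Over the narrow hue band
#' plants occupy (about -0.02 to 0.25) the unwrap makes hue a continuous
#' linear axis, so the arithmetic mean composes exactly with the linear
#' pigment calibrations (averaging hue then converting equals converting
#' per pixel then averaging).
#'
#' @param mask logical cell-local mask.
#' @param hsv full-image [rgb_to_hsv_image()] result.
#' @param cell_rect the cell bounds `(x0, y0, x1, y1)`, 0-based half-open.
#' @return Mean unwrapped hue, or `NA` (with a warning) for an empty mask.
#' @export
plant_mean_hue <- function(mask, hsv, cell_rect = c(0, 0, ncol(hsv$hue), nrow(hsv$hue))) {
  if (!any(mask)) {
    warn("empty mask: mean hue undefined.", class = "phenoplate_empty_mask")
    return(NA_real_)
  }
  sub <- hsv$hue[(cell_rect[2] + 1):cell_rect[4],
                 (cell_rect[1] + 1):cell_rect[3], drop = FALSE]
  stopifnot(identical(dim(sub), dim(mask)))
  mean(unwrap_hue(sub[mask]))
}

#' Estimate chlorophyll content from mean hue
#'
#' Applies a fitted hue-to-chlorophyll linear calibration. The linear
#' relation holds over a bounded chlorophyll range (default 0.2--1.0
#' ug/pixel); predictions outside it are returned but flagged out-of-range,
#' and negative values are clipped to 0.
#'
#' @param mean_hue mean unwrapped hue value(s).
#' @param model a `cal_model` from [calibrate_pigment()].
#' @param response_range valid chlorophyll range in ug/pixel.
#' @return A tibble with `chl_per_px` and `in_range`.
#' @export
estimate_chlorophyll <- function(mean_hue, model, response_range = c(0.2, 1.0)) {
  if (is.null(model)) {
    abort("no chlorophyll calibration model supplied; fit one with calibrate_pigment().")
  }
  stopifnot(inherits(model, "cal_model"))
  chl <- model$intercept + model$slope * mean_hue
  in_range <- !is.na(chl) & chl >= response_range[1] & chl <= response_range[2]
  if (any(!in_range & !is.na(chl))) {
    warn(sprintf("%d chlorophyll estimate(s) outside the calibrated range [%g, %g] ug/px.",
                 sum(!in_range & !is.na(chl)), response_range[1], response_range[2]),
         class = "phenoplate_out_of_range")
  }
  neg <- !is.na(chl) & chl < 0
  chl[neg] <- 0
  tibble(chl_per_px = chl, in_range = in_range)
}

#' Estimate anthocyanin content from mean hue
#'
#' Anthocyanin accumulation shifts leaf color from green toward red, i.e.
#' to lower unwrapped hue, so a valid calibration has negative slope and
#' the estimate decreases monotonically with hue. Negative predictions are
#' clipped to 0.
#'
#' @param mean_hue mean unwrapped hue value(s).
#' @param model a `cal_model` from [calibrate_pigment()] (negative slope
#'   expected; a non-negative slope triggers a warning).
#' @return Anthocyanin estimate(s) per pixel (same units as the calibration
#'   response), clipped at 0.
#' @export
estimate_anthocyanin <- function(mean_hue, model) {
  if (is.null(model)) {
    abort("no anthocyanin calibration model supplied; fit one with calibrate_pigment().")
  }
  stopifnot(inherits(model, "cal_model"))
  if (model$slope >= 0) {
    warn("anthocyanin model has non-negative slope; expected a reverse hue correlation.",
         class = "phenoplate_reverse_correlation")
  }
  anth <- model$intercept + model$slope * mean_hue
  pmax(anth, 0)
}
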