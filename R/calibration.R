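# Linear calibration models: area -> fresh weight, hue -> chlorophyll,
# hue -> anthocyanin; JSON persistence; broom-style accessors.

new_cal_model <- function(slope, intercept, r_squared, n_points, valid_range,
                          kind = "generic", fitted_on = format(Sys.Date())) {
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         n_points = as.integer(n_points),
         valid_range = as.numeric(valid_range),
         kind = kind, fitted_on = fitted_on),
    class = "cal_model"
  )
}

#' Fit a simple linear calibration by ordinary least squares
#'
#' Fits `y = intercept + slope * x` with [stats::lm()] and records the fit
#' statistics needed to judge a calibration: R-squared, number of points,
#' and the predictor range over which the model is valid (extrapolation
#' beyond `valid_range` is the caller's risk). A constant response gives
#' R-squared 0 by convention, with a warning.
#'
#' @param data data frame holding predictor and response.
#' @param x,y column names (tidy evaluation) of predictor and response.
#' @param kind label stored on the model (`"weight"`, `"chlorophyll"`,
#'   `"anthocyanin"`, or `"generic"`).
#' @return A `cal_model`: slope, intercept, `r_squared`, `n_points`,
#'   `valid_range`, `kind`, `fitted_on`.
#' @export
fit_linear <- function(data, x, y, kind = "generic") {
  df <- as_tibble(data)
  xv <- dplyr::pull(df, {{ x }})
  yv <- dplyr::pull(df, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 2) abort("at least 2 complete (x, y) pairs are required.")
  if (length(unique(xv)) < 2) {
    abort("predictor is constant: slope is not identifiable.")
  }
  fit <- stats::lm(yv ~ xv)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) {
    warn("response is constant; R-squared set to 0 by convention.",
         class = "phenoplate_constant_response")
    r2 <- 0
  }
  cf <- coef(fit)
  new_cal_model(
    slope = unname(cf[2]), intercept = unname(cf[1]), r_squared = r2,
    n_points = length(xv), valid_range = range(xv), kind = kind
  )
}

#' Calibrate pixel area against fresh weight
#'
#' Fits fresh weight (mg) on pixel area measured at the 3000 x 4000
#' reference frame. Weigh a spread of plant sizes; calibrations built from
#' two to three hundred plantlets give stable slopes (a reference-quality
#' run used 250), so fewer than 200 pairs triggers a small-n warning.
#' Areas measured at other image sizes should be normalised first
#' (`area_px * 12e6 / image_px_total`).
#'
#' @param pairs data frame with columns `area_px` and `fresh_weight_mg`.
#' @return A `cal_model` with kind `"weight"` (slope in mg per
#'   reference-frame pixel).
#' @export
calibrate_weight <- function(pairs) {
  df <- as_tibble(pairs)
  if (!all(c("area_px", "fresh_weight_mg") %in% names(df))) {
    abort("pairs must have columns area_px and fresh_weight_mg.")
  }
  if (nrow(df) < 200) {
    warn(sprintf("weight calibration from only %d pairs; 200-300 plantlets recommended.",
                 nrow(df)),
         class = "phenoplate_small_n_calib")
  }
  fit_linear(df, x = .data$area_px, y = .data$fresh_weight_mg, kind = "weight")
}

#' Calibrate mean hue against pigment content
#'
#' Fits pigment content per pixel on mean unwrapped hue, from plants that
#' were photographed and then assayed chemically ([lichtenthaler()] /
#' [ph_differential()]). Chlorophyll rises with hue over the green band
#' (positive slope); anthocyanin shows the reverse correlation, so a
#' non-negative anthocyanin slope is flagged. Around three hundred plants
#' spanning the color range give satisfactory calibrations.
#'
#' @param pairs data frame with columns `mean_hue` and `pigment`.
#' @param kind `"chlorophyll"` or `"anthocyanin"`.
#' @return A `cal_model`.
#' @export
calibrate_pigment <- function(pairs, kind = c("chlorophyll", "anthocyanin")) {
  kind <- match.arg(kind)
  df <- as_tibble(pairs)
  if (!all(c("mean_hue", "pigment") %in% names(df))) {
    abort("pairs must have columns mean_hue and pigment.")
  }
  if (nrow(df) < 200) {
    warn(sprintf("%s calibration from only %d pairs; 200-300 plants recommended.",
                 kind, nrow(df)),
         class = "phenoplate_small_n_calib")
  }
  m <- fit_linear(df, x = .data$mean_hue, y = .data$pigment, kind = kind)
  if (kind == "anthocyanin" && m$slope >= 0) {
    warn("anthocyanin calibration has non-negative slope; expected a reverse hue correlation.",
         class = "phenoplate_reverse_correlation")
  }
  m
}

#' @export
print.cal_model <- function(x, ...) {
  cat(sprintf("<cal_model: %s>\n", x$kind))
  cat(sprintf("  y = %.6g + %.6g * x   (R^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n_points))
  cat(sprintf("  valid predictor range: [%.6g, %.6g]\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' @describeIn fit_linear tidy coefficient table for a `cal_model`.
#' @param x a `cal_model`.
#' @param ... unused.
#' @export
tidy.cal_model <- function(x, ...) {
  tibble(term = c("(Intercept)", "slope"), estimate = c(x$intercept, x$slope))
}

#' @describeIn fit_linear one-row fit summary for a `cal_model`.
#' @export
glance.cal_model <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, nobs = x$n_points, kind = x$kind,
    range_lo = x$valid_range[1], range_hi = x$valid_range[2]
  )
}

#' Predict from a calibration model
#'
#' @param object a `cal_model`.
#' @param newdata numeric vector of predictor values.
#' @param ... unused.
#' @return Numeric predictions (no clipping; clipping policy belongs to the
#'   pigment/weight wrappers).
#' @export
predict.cal_model <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' Bundle and persist calibration models
#'
#' A calibration set holds the up-to-three models a run needs (weight,
#' chlorophyll, anthocyanin); any may be `NULL`, in which case the
#' corresponding record columns stay `NA`. Sets round-trip through a JSON
#' file (`slope`, `intercept`, `r_squared`, `n_points`, `valid_range`,
#' `kind`, `fitted_on` per model).
#'
#' @param weight,chlorophyll,anthocyanin `cal_model` objects or `NULL`.
#' @return A `calibration_set`.
#' @export
calibration_set <- function(weight = NULL, chlorophyll = NULL, anthocyanin = NULL) {
  for (m in list(weight, chlorophyll, anthocyanin)) {
    if (!is.null(m) && !inherits(m, "cal_model")) {
      abort("calibration_set components must be cal_model objects or NULL.")
    }
  }
  structure(
    list(weight = weight, chlorophyll = chlorophyll, anthocyanin = anthocyanin),
    class = "calibration_set"
  )
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("<calibration_set>\n")
  for (nm in c("weight", "chlorophyll", "anthocyanin")) {
    if (is.null(x[[nm]])) cat(sprintf("  %s: <none>\n", nm))
    else cat(sprintf("  %s: slope %.6g, intercept %.6g (R^2 %.4f, n %d)\n",
                     nm, x[[nm]]$slope, x[[nm]]$intercept,
                     x[[nm]]$r_squared, x[[nm]]$n_points))
  }
  invisible(x)
}

cal_model_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  list(slope = m$slope, intercept = m$intercept, r_squared = m$r_squared,
       n_points = m$n_points, valid_range = m$valid_range, kind = m$kind,
       fitted_on = m$fitted_on)
}

cal_model_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  new_cal_model(l$slope, l$intercept, l$r_squared, l$n_points,
                unlist(l$valid_range), l$kind %||% "generic",
                l$fitted_on %||% NA_character_)
}

#' @rdname calibration_set
#' @param set a `calibration_set` (or single `cal_model`).
#' @param path JSON file path.
#' @export
write_calibration <- function(set, path) {
  if (inherits(set, "cal_model")) set <- calibration_set(weight = set)
  stopifnot(inherits(set, "calibration_set"))
  out <- Filter(Negate(is.null), lapply(set, cal_model_to_list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname calibration_set
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(sprintf("calibration file does not exist: '%s'", path))
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  calibration_set(
    weight = cal_model_from_list(l$weight),
    chlorophyll = cal_model_from_list(l$chlorophyll),
    anthocyanin = cal_model_from_list(l$anthocyanin)
  )
}
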