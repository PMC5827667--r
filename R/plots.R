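# ggplot2 visual summaries for fitted models and result tables.

#' @describeIn fit_linear scatter + fitted line for a calibration model.
#'   `data`, `x`, `y` optionally overlay the calibration points.
#' @param object a `cal_model`.
#' @param data optional data frame of calibration pairs to overlay.
#' @export
autoplot.cal_model <- function(object, data = NULL, x = NULL, y = NULL, ...) {
  rng <- object$valid_range
  line_df <- tibble(
    x = seq(rng[1], rng[2], length.out = 100),
    y = object$intercept + object$slope * seq(rng[1], rng[2], length.out = 100)
  )
  p <- ggplot2::ggplot(line_df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(color = "steelblue", linewidth = 1) +
    ggplot2::labs(
      title = sprintf("%s calibration", object$kind),
      subtitle = sprintf("y = %.4g + %.4g x,  R² = %.3f, n = %d",
                         object$intercept, object$slope, object$r_squared,
                         object$n_points),
      x = "predictor", y = "response"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    pts <- tibble(
      x = dplyr::pull(as_tibble(data), {{ x }}),
      y = dplyr::pull(as_tibble(data), {{ y }})
    )
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.4)
  }
  p
}

#' @describeIn growth_rate log-scale growth trajectory with the fitted
#'   exponential.
#' @param object a `growth_fit`.
#' @param series optional the original series data frame to overlay.
#' @export
autoplot.growth_fit <- function(object, series = NULL, time = time, area = area, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      title = sprintf("Growth factor %.3f per unit time (R² = %.3f)",
                      object$factor, object$r_squared),
      x = "time (days)", y = "area (px, log scale)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(series)) {
    df <- tibble(
      t = dplyr::pull(as_tibble(series), {{ time }}),
      a = dplyr::pull(as_tibble(series), {{ area }})
    )
    fit_df <- tibble(
      t = seq(min(df$t), max(df$t), length.out = 100),
      a = exp(object$log_intercept + object$log_slope *
                seq(min(df$t), max(df$t), length.out = 100))
    )
    p <- p +
      ggplot2::geom_point(data = df, ggplot2::aes(x = .data$t, y = .data$a)) +
      ggplot2::geom_line(data = fit_df, ggplot2::aes(x = .data$t, y = .data$a),
                         color = "steelblue")
  }
  p
}

#' @describeIn run_batch per-row-name boxplots of a chosen metric.
#' @param object a `plate_results`.
#' @param metric record column to plot (default `area_px`).
#' @export
autoplot.plate_results <- function(object, metric = area_px, ...) {
  df <- object$records |> filter(.data$area_px > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row_name, y = {{ metric }})) +
    ggplot2::geom_boxplot(fill = "palegreen3", alpha = 0.6, outlier.alpha = 0.4) +
    ggplot2::labs(x = "row (genotype)", title = "Per-row distribution") +
    ggplot2::theme_minimal()
}
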