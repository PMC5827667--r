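# Exponential growth-rate estimation from area (or weight) time series.

#' Exponential growth rate of an area time series
#'
#' Young rosettes grow approximately exponentially, so the per-day growth
#' factor is estimated by ordinary least squares on the log scale:
#' `ln(area) = a + b t`, and the factor is `exp(b)` (the base returned by
#' spreadsheet exponential regression, e.g. a factor of 2.0 means the
#' rosette doubles per unit time). The factor is invariant to rescaling all
#' areas by a constant, and to shifting the time origin.
#'
#' @param series data frame with a time column (days) and a positive area
#'   (or weight) column.
#' @param time,area column names (tidy evaluation); defaults `time`, `area`.
#' @return A `growth_fit`: list with `factor` (per unit time), `log_slope`,
#'   `log_intercept`, `r_squared` (of the log-scale fit), `n`.
#' @export
growth_rate <- function(series, time = time, area = area) {
  df <- as_tibble(series)
  tv <- dplyr::pull(df, {{ time }})
  av <- dplyr::pull(df, {{ area }})
  if (length(tv) < 2) abort("at least 2 time points are required.")
  bad <- which(!is.finite(av) | av <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive area at time point(s): %s (log growth fit undefined).",
                  paste(tv[bad], collapse = ", ")))
  }
  if (length(unique(tv)) < 2) abort("time values must not all be equal.")
  fit <- stats::lm(log(av) ~ tv)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 0
  cf <- coef(fit)
  structure(
    list(factor = exp(unname(cf[2])), log_slope = unname(cf[2]),
         log_intercept = unname(cf[1]), r_squared = r2, n = length(tv)),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> factor %.4f per unit time (R^2 %.4f, n %d)\n",
              x$factor, x$r_squared, x$n))
  invisible(x)
}

#' @describeIn growth_rate tidy one-row coefficient table.
#' @param x a `growth_fit`.
#' @param ... unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("log_intercept", "log_slope"),
         estimate = c(x$log_intercept, x$log_slope))
}

#' @describeIn growth_rate one-row fit summary.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(growth_factor = x$factor, r.squared = x$r_squared, nobs = x$n)
}

#' Growth rates by group from a combined record table
#'
#' Convenience wrapper fitting [growth_rate()] within each group of a long
#' table (e.g. the combined output of a batch run joined with sampling
#' days). Cells with zero area are dropped before fitting; groups left with
#' fewer than 2 points return `NA`.
#'
#' @param data a long data frame.
#' @param time,area column names (tidy evaluation).
#' @param ... grouping columns (tidy evaluation), e.g. `row_name`.
#' @return A tibble with the grouping columns plus `growth_factor`,
#'   `r_squared`, `n_points`.
#' @export
growth_rates <- function(data, time = time, area = area_px, ...) {
  df <- as_tibble(data)
  df |>
    dplyr::group_by(...) |>
    dplyr::group_modify(function(d, key) {
      av <- dplyr::pull(d, {{ area }})
      d <- d[is.finite(av) & av > 0, , drop = FALSE]
      if (nrow(d) < 2 || length(unique(dplyr::pull(d, {{ time }}))) < 2) {
        return(tibble(growth_factor = NA_real_, r_squared = NA_real_,
                      n_points = nrow(d)))
      }
      g <- growth_rate(d, time = {{ time }}, area = {{ area }})
      tibble(growth_factor = g$factor, r_squared = g$r_squared, n_points = g$n)
    }) |>
    dplyr::ungroup()
}
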