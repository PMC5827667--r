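# Wet-chemistry reference computations, linear calibration fits, and
# growth-rate estimation.

test_that("chlorophyll equations reproduce their unit responses", {
  r1 <- lichtenthaler(tibble::tibble(a470 = 0, a648_6 = 0, a664_1 = 1))
  expect_equal(r1$chl_a, 13.36)
  expect_equal(r1$chl_b, -8.12)
  r2 <- lichtenthaler(tibble::tibble(a470 = 0, a648_6 = 1, a664_1 = 0))
  expect_equal(r2$chl_b, 27.43)
  expect_equal(r2$chl_a, -5.19)
  r3 <- lichtenthaler(tibble::tibble(a470 = 0.5, a648_6 = 0.2, a664_1 = 0.5))
  expect_equal(r3$chl_a, 13.36 * 0.5 - 5.19 * 0.2)
  expect_equal(r3$chl_a, 5.642)
  expect_equal(r3$chl_b, 27.43 * 0.2 - 8.12 * 0.5)
  expect_equal(r3$chl_b, 1.426)
  expect_equal(r3$chl_total, 7.068)
  expect_equal(r3$carotenoids, (1000 * 0.5 - 2.13 * 5.642 - 97.64 * 1.426) / 209)
})

test_that("chl_total is exactly chl_a + chl_b and OD flags are set", {
  set.seed(21)
  df <- tibble::tibble(
    a470 = runif(50, 0, 1.2), a648_6 = runif(50, 0, 1.2), a664_1 = runif(50, 0, 1.2)
  )
  out <- lichtenthaler(df)
  expect_identical(out$chl_total, out$chl_a + out$chl_b)
  expect_equal(out$od_ok,
               df$a648_6 >= 0.3 & df$a648_6 <= 0.8 & df$a664_1 >= 0.3 & df$a664_1 <= 0.8)
  expect_error(lichtenthaler(tibble::tibble(a470 = 1)), "missing absorbance")
  expect_error(lichtenthaler(tibble::tibble(a470 = -1, a648_6 = 0, a664_1 = 0)),
               "non-negative")
})

test_that("pH-differential anthocyanin follows the printed formula", {
  u <- ph_differential(tibble::tibble(
    a520_ph1 = 1.1, a700_ph1 = 0.1, a520_ph45 = 0.1, a700_ph45 = 0.1
  ))
  expect_equal(u$adiff, 1.0)
  expect_equal(u$anthocyanin_mg_l, 83.5)

  z <- ph_differential(tibble::tibble(
    a520_ph1 = 0.4, a700_ph1 = 0.4, a520_ph45 = 0.4, a700_ph45 = 0.4
  ))
  expect_equal(z$anthocyanin_mg_l, 0)

  d <- ph_differential(tibble::tibble(
    a520_ph1 = 0.80, a700_ph1 = 0.05, a520_ph45 = 0.20, a700_ph45 = 0.05
  ))
  expect_equal(d$adiff, 0.60)
  expect_equal(d$anthocyanin_mg_l, 50.1)

  expect_warning(
    neg <- ph_differential(tibble::tibble(
      a520_ph1 = 0.1, a700_ph1 = 0.05, a520_ph45 = 0.8, a700_ph45 = 0.05
    )),
    "negative"
  )
  expect_true(neg$adiff_negative)
  expect_equal(neg$anthocyanin_mg_l, 0)
})

test_that("pH-differential is linear in each absorbance with the printed signs", {
  base <- tibble::tibble(a520_ph1 = 0.5, a700_ph1 = 0.1, a520_ph45 = 0.2, a700_ph45 = 0.1)
  f <- function(df) ph_differential(df)$adiff
  eps <- 0.01
  expect_equal(f(dplyr::mutate(base, a520_ph1 = a520_ph1 + eps)) - f(base), eps)
  expect_equal(f(dplyr::mutate(base, a700_ph1 = a700_ph1 + eps)) - f(base), -eps)
  expect_equal(f(dplyr::mutate(base, a520_ph45 = a520_ph45 + eps)) - f(base), -eps)
  expect_equal(f(dplyr::mutate(base, a700_ph45 = a700_ph45 + eps)) - f(base), eps)
  # per-FW normalization with the 200 uL extraction volume
  fw <- ph_differential(dplyr::mutate(base, fresh_weight_mg = 10))
  expect_equal(fw$anth_ug_per_mg_fw, fw$anthocyanin_mg_l * 0.2 / 10)
})

test_that("fit_linear recovers exact lines and matches the normal equations", {
  df <- tibble::tibble(x = 1:5, y = 2 * (1:5) + 1)
  m <- fit_linear(df, x, y)
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 1)
  expect_equal(m$r_squared, 1)
  expect_equal(m$valid_range, c(1, 5))
  expect_equal(m$n_points, 5L)

  expect_warning(mc <- fit_linear(tibble::tibble(x = 1:4, y = rep(3, 4)), x, y),
                 "constant")
  expect_equal(mc$slope, 0)
  expect_equal(mc$r_squared, 0)
  expect_error(fit_linear(tibble::tibble(x = rep(2, 5), y = 1:5), x, y),
               "constant")

  set.seed(1234)
  for (rep in 1:8) {
    xs <- rnorm(20); ys <- rnorm(20)
    m2 <- fit_linear(tibble::tibble(x = xs, y = ys), x, y)
    o <- oracle_ols(xs, ys)
    expect_equal(m2$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(m2$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
})

test_that("noisy linear data recovers the generating slope (n = 300)", {
  set.seed(2024)
  x <- runif(300, 0, 10)
  y <- 2 * x + 1 + rnorm(300, 0, 0.1)
  m <- fit_linear(tibble::tibble(x = x, y = y), x, y)
  expect_gte(m$slope, 1.98)
  expect_lte(m$slope, 2.02)
  expect_gt(m$r_squared, 0.99)
})

test_that("growth_rate returns the per-day factor of exponential series", {
  doubling <- tibble::tibble(time = 0:3, area = c(100, 200, 400, 800))
  g <- growth_rate(doubling)
  expect_equal(g$factor, 2.0)
  expect_equal(g$r_squared, 1)

  flat <- tibble::tibble(time = 0:4, area = rep(500, 5))
  expect_equal(growth_rate(flat)$factor, 1.0)

  set.seed(77)
  t <- 0:9
  noisy <- tibble::tibble(time = t, area = 100 * 1.5^t * exp(rnorm(10, 0, 0.05)))
  gn <- growth_rate(noisy)
  expect_gte(gn$factor, 1.45)
  expect_lte(gn$factor, 1.55)

  expect_error(growth_rate(tibble::tibble(time = 0:2, area = c(10, 0, 40))),
               "non-positive")
})

test_that("growth_rate is invariant to area scaling and equivariant to time shift", {
  set.seed(31)
  t <- seq(0, 12, by = 3)
  a <- 50 * 1.3^t * exp(rnorm(length(t), 0, 0.02))
  g0 <- growth_rate(tibble::tibble(time = t, area = a))
  g_scaled <- growth_rate(tibble::tibble(time = t, area = 1000 * a))
  g_shifted <- growth_rate(tibble::tibble(time = t + 5, area = a))
  expect_equal(g_scaled$factor, g0$factor, tolerance = 1e-12)
  expect_equal(g_shifted$factor, g0$factor, tolerance = 1e-9)
})

test_that("parameter recovery improves as calibration size grows", {
  set.seed(55)
  rmse_at <- function(n, reps = 20) {
    errs <- replicate(reps, {
      x <- runif(n, 1000, 30000)
      y <- x / 1600 + rnorm(n, 0, 0.5)
      m <- fit_linear(tibble::tibble(x = x, y = y), x, y)
      m$slope - 1 / 1600
    })
    sqrt(mean(errs^2))
  }
  expect_gt(rmse_at(10), rmse_at(300))
})

test_that("weight calibration warns on small n and recovers a known slope", {
  line <- tibble::tibble(area_px = seq(800, 48000, length.out = 250),
                         fresh_weight_mg = seq(800, 48000, length.out = 250) / 1600)
  m <- suppressWarnings(calibrate_weight(line))
  expect_equal(m$slope, 1 / 1600)
  expect_equal(m$kind, "weight")

  expect_warning(calibrate_weight(tibble::tibble(area_px = c(1000, 2000),
                                                 fresh_weight_mg = c(0.6, 1.2))),
                 "200-300")

  set.seed(999)
  noisy <- tibble::tibble(
    area_px = runif(250, 1000, 40000),
    fresh_weight_mg = runif(250, 1000, 40000) * 0 + NA
  )
  noisy$fresh_weight_mg <- noisy$area_px / 1600 + rnorm(250, 0, 1)
  mn <- calibrate_weight(noisy)
  expect_equal(mn$slope, 1 / 1600, tolerance = 0.03)
})

test_that("pigment calibration records validity ranges and flags reversed slopes", {
  exact <- tibble::tibble(mean_hue = seq(0.05, 0.25, length.out = 10),
                          pigment = 4 * seq(0.05, 0.25, length.out = 10))
  m <- suppressWarnings(calibrate_pigment(exact, "chlorophyll"))
  expect_equal(m$slope, 4)
  expect_equal(m$r_squared, 1)
  expect_equal(m$valid_range, c(0.05, 0.25))

  pos <- tibble::tibble(mean_hue = c(0, 0.1, 0.2), pigment = c(0, 1, 2))
  expect_warning(suppressWarnings(calibrate_pigment(pos, "anthocyanin"),
                                  classes = "phenoplate_small_n_calib"),
                 "reverse")

  # a hue band mapped into the valid chlorophyll response range stays unflagged
  set.seed(4)
  hue <- runif(300, 0.05, 0.25)
  pig <- 0.2 + (hue - 0.05) / 0.2 * 0.8 + rnorm(300, 0, 0.01)
  mc <- calibrate_pigment(tibble::tibble(mean_hue = hue, pigment = pig), "chlorophyll")
  preds <- suppressWarnings(estimate_chlorophyll(seq(0.06, 0.24, 0.02), mc))
  expect_true(all(preds$in_range))
})

test_that("calibration sets round-trip through JSON", {
  w <- fit_linear(tibble::tibble(x = c(0, 1600), y = c(0, 1)), x, y, kind = "weight")
  ch <- fit_linear(tibble::tibble(x = c(0.05, 0.25), y = c(0.2, 1.0)), x, y,
                   kind = "chlorophyll")
  set <- calibration_set(weight = w, chlorophyll = ch)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(set, path)
  back <- read_calibration(path)
  expect_equal(back$weight$slope, w$slope, tolerance = 1e-12)
  expect_equal(back$weight$intercept, w$intercept, tolerance = 1e-12)
  expect_equal(back$chlorophyll$valid_range, ch$valid_range)
  expect_null(back$anthocyanin)
  expect_s3_class(tidy(back$weight), "tbl_df")
  expect_equal(glance(back$chlorophyll)$kind, "chlorophyll")
})
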