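# Wet-chemistry reference assays that produce the calibration truth:
# spectrophotometric chlorophyll/carotenoid equations and the
# pH-differential anthocyanin assay.

#' Chlorophyll and carotenoid concentrations from extract absorbances
#'
#' Converts optical densities of an ethanolic leaf extract measured at
#' 470, 648.6 and 664.1 nm into pigment concentrations (ug/mL):
#'
#' \deqn{Chl_a = 13.36\,A_{664.1} - 5.19\,A_{648.6}}
#' \deqn{Chl_b = 27.43\,A_{648.6} - 8.12\,A_{664.1}}
#' \deqn{Car = (1000\,A_{470} - 2.13\,Chl_a - 97.64\,Chl_b)/209}
#'
#' Total chlorophyll is `chl_a + chl_b` exactly. Raw values are returned;
#' negative concentrations (possible with unusual OD combinations) are
#' flagged, not altered. Spectrophotometer readings are most reliable for
#' ODs between 0.3 and 0.8; readings outside that window are flagged in
#' `od_ok`. When `extract_volume_ml` and `fresh_weight_mg` columns are
#' present, per-fresh-weight values (ug/mg FW) are added.
#'
#' @param absorbances data frame with columns `a470`, `a648_6`, `a664_1`
#'   and optionally `fresh_weight_mg`, `extract_volume_ml`.
#' @return The input as a tibble with added columns `chl_a`, `chl_b`,
#'   `chl_total`, `carotenoids` (ug/mL), `od_ok`, `negative_flag`, and
#'   `chl_total_per_fw` (ug/mg FW) when volume and weight are supplied.
#' @export
lichtenthaler <- function(absorbances) {
  df <- as_tibble(absorbances)
  need <- c("a470", "a648_6", "a664_1")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("missing absorbance column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyNA(df[need])) abort("absorbance columns contain missing values.")
  if (any(df$a470 < 0 | df$a648_6 < 0 | df$a664_1 < 0)) {
    abort("absorbances must be non-negative.")
  }
  df <- df |>
    mutate(
      chl_a = 13.36 * .data$a664_1 - 5.19 * .data$a648_6,
      chl_b = 27.43 * .data$a648_6 - 8.12 * .data$a664_1,
      chl_total = .data$chl_a + .data$chl_b,
      carotenoids = (1000 * .data$a470 - 2.13 * .data$chl_a - 97.64 * .data$chl_b) / 209,
      od_ok = .data$a648_6 >= 0.3 & .data$a648_6 <= 0.8 &
        .data$a664_1 >= 0.3 & .data$a664_1 <= 0.8,
      negative_flag = .data$chl_a < 0 | .data$chl_b < 0 | .data$carotenoids < 0
    )
  if (all(c("fresh_weight_mg", "extract_volume_ml") %in% names(df))) {
    df <- df |>
      mutate(chl_total_per_fw = .data$chl_total * .data$extract_volume_ml / .data$fresh_weight_mg)
  }
  df
}

#' Monomeric anthocyanin by the pH-differential method
#'
#' Monomeric anthocyanins change color reversibly between pH 1.0 and
#' pH 4.5 while interfering pigments do not. With absorbances of the two
#' buffered aliquots read at 520 and 700 nm,
#' `adiff = (A520 - A700)_pH1.0 - (A520 - A700)_pH4.5` and the monomeric
#' anthocyanin concentration is `adiff * 83.5` mg/L. A negative `adiff`
#' (typically swapped buffers) is flagged and the concentration clipped
#' to 0. When `fresh_weight_mg` is present, the per-fresh-weight value is
#' computed from the extraction volume (default 200 uL water per plant).
#'
#' @param absorbances data frame with columns `a520_ph1`, `a700_ph1`,
#'   `a520_ph45`, `a700_ph45` and optionally `fresh_weight_mg`.
#' @param extract_volume_ul extraction volume per plant in uL (default 200).
#' @return The input as a tibble with added columns `adiff`,
#'   `anthocyanin_mg_l`, `adiff_negative`, and `anth_ug_per_mg_fw` when
#'   fresh weights are supplied.
#' @export
ph_differential <- function(absorbances, extract_volume_ul = 200) {
  df <- as_tibble(absorbances)
  need <- c("a520_ph1", "a700_ph1", "a520_ph45", "a700_ph45")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("missing absorbance column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyNA(df[need])) abort("absorbance columns contain missing values.")
  if (any(as.matrix(df[need]) < 0)) abort("absorbances must be non-negative.")
  df <- df |>
    mutate(
      adiff = (.data$a520_ph1 - .data$a700_ph1) - (.data$a520_ph45 - .data$a700_ph45),
      adiff_negative = .data$adiff < 0,
      anthocyanin_mg_l = pmax(.data$adiff, 0) * 83.5
    )
  if (any(df$adiff_negative)) {
    warn(sprintf("%d sample(s) with negative pH-differential absorbance (buffers swapped?); clipped to 0.",
                 sum(df$adiff_negative)),
         class = "phenoplate_negative_adiff")
  }
  if ("fresh_weight_mg" %in% names(df)) {
    # mg/L * (volume in L) = mg anthocyanin; per mg FW; reported in ug/mg FW
    df <- df |>
      mutate(anth_ug_per_mg_fw = .data$anthocyanin_mg_l * (extract_volume_ul * 1e-6) * 1000 /
               .data$fresh_weight_mg)
  }
  df
}
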