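Package: phenoplate
Title: Plate-Based Plant Phenotyping from Color Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures size, shape and color of multiple in-vitro grown
    plantlets per photograph. Plates of plants arranged in a grid on a white
    background are segmented in HSV space, each grid cell yields one plant
    record with pixel area, convex area, convex ratio and mean hue, and
    linear calibration models convert pixel area to fresh weight and mean
    hue to chlorophyll or anthocyanin content. Includes the
    spectrophotometric reference computations used to build the pigment
    calibrations (chlorophyll a/b/carotenoid equations and the
    pH-differential anthocyanin assay), log-linear growth-rate estimation,
    a synthetic plate generator with exact ground truth for validation, and
    batch export to CSV and Excel-compatible workbooks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
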