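# Shared internal helpers: rectangle handling, warning codes, small numerics.

# Rectangles are 0-based, half-open: (x0, y0, x1, y1) selects columns
# x0+1..x1 and rows y0+1..y1 of the pixel matrix (row 1 = top of image).

rect_width <- function(r) r[3] - r[1]
rect_height <- function(r) r[4] - r[2]

validate_rect <- function(rect, width, height) {
  if (length(rect) != 4 || any(!is.finite(rect))) {
    abort("analysis_rect must be four finite numbers (x0, y0, x1, y1).")
  }
  rect <- as.integer(rect)
  if (rect[1] < 0 || rect[2] < 0 || rect[3] > width || rect[4] > height ||
      rect[1] >= rect[3] || rect[2] >= rect[4]) {
    abort(sprintf(
      "analysis_rect (%d, %d, %d, %d) is not a non-empty rectangle inside the %dx%d image.",
      rect[1], rect[2], rect[3], rect[4], width, height
    ))
  }
  rect
}

# Split the integer interval [lo, hi) into k spans as evenly as integer
# division allows; the first (hi-lo) %% k spans take the extra pixel.
split_interval <- function(lo, hi, k) {
  n <- hi - lo
  base <- n %/% k
  widths <- rep.int(base, k)
  r <- n %% k
  if (r > 0) widths[seq_len(r)] <- widths[seq_len(r)] + 1L
  edges <- lo + cumsum(c(0L, widths))
  cbind(start = edges[-(k + 1)], end = edges[-1])
}

# Stable warning codes accumulated per plant record.
WARN_CODES <- c(
  "EMPTY_CELL", "EDGE_TOUCH", "OUT_OF_RANGE_CHL", "NEGATIVE_CLIPPED",
  "SMALL_N_CALIB", "NO_FOREGROUND", "SHAPE_CAPPED", "REVERSE_CORRELATION"
)

join_warn <- function(codes) {
  codes <- unique(codes[nzchar(codes)])
  if (length(codes) == 0) "" else paste(codes, collapse = ";")
}

add_warn <- function(existing, code) {
  vapply(existing, function(w) {
    join_warn(c(strsplit(w, ";", fixed = TRUE)[[1]], code))
  }, character(1), USE.NAMES = FALSE)
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
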