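# Independent oracles used to validate the package's computations.
# These deliberately re-derive each quantity from first principles and do
# not call the implementation paths they check.

# Scalar hexcone RGB (0-255) -> HSV, straight from the piecewise definition.
oracle_rgb2hsv <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  v <- mx
  s <- if (mx == 0) 0 else d / mx
  h <- if (d == 0) {
    0
  } else if (mx == r) {
    ((g - b) / d) %% 6
  } else if (mx == g) {
    (b - r) / d + 2
  } else {
    (r - g) / d + 4
  }
  c(h = (h / 6) %% 1, s = s, v = v)
}

# Brute-force convex-hull membership: a lattice point is in the hull of the
# mask's points iff it coincides with one, lies on a segment between two,
# or lies inside a triangle of three (Caratheodory in 2D). O(n^3) per point.
oracle_point_in_hull <- function(x, y, pts) {
  n <- nrow(pts)
  if (any(pts[, 1] == x & pts[, 2] == y)) return(TRUE)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]
      cr <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
      if (abs(cr) < 1e-9 &&
          (x - a[1]) * (x - b[1]) + (y - a[2]) * (y - b[2]) <= 1e-9) {
        return(TRUE)
      }
    }
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
      tri2 <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (abs(tri2) < 1e-9) next   # degenerate triangle: covered by segments
      d1 <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
      d2 <- (c[1] - b[1]) * (y - b[2]) - (c[2] - b[2]) * (x - b[1])
      d3 <- (a[1] - c[1]) * (y - c[2]) - (a[2] - c[2]) * (x - c[1])
      if ((d1 >= -1e-9 && d2 >= -1e-9 && d3 >= -1e-9) ||
          (d1 <= 1e-9 && d2 <= 1e-9 && d3 <= 1e-9)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

oracle_hull_pixel_count <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  pts <- cbind(idx[, 2], idx[, 1])
  cnt <- 0L
  for (y in seq_len(nrow(mask))) {
    for (x in seq_len(ncol(mask))) {
      if (oracle_point_in_hull(x, y, pts)) cnt <- cnt + 1L
    }
  }
  cnt
}

# Even-odd ray casting, independent of the pracma rasterizer.
oracle_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((py[i] > y) != (py[j] > y)) {
      xint <- px[i] + (y - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = b[1], slope = b[2])
}

# Random sparse mask with n points inside an h x w window.
random_mask <- function(h, w, n) {
  m <- matrix(FALSE, h, w)
  pick <- sample(h * w, min(n, h * w))
  m[pick] <- TRUE
  m
}

# Uniform-color plate: a single rectangle of the given 0-255 RGB color on
# near-white background, sized h x w.
solid_patch_plate <- function(h, w, rect, rgb, background = c(252, 252, 252)) {
  px <- array(0, dim = c(h, w, 3))
  for (c in 1:3) px[, , c] <- background[c]
  rows <- (rect[2] + 1):rect[4]; cols <- (rect[1] + 1):rect[3]
  for (c in 1:3) px[rows, cols, c] <- rgb[c]
  plate_image(px)
}
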