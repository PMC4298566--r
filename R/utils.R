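# Small numeric helpers shared across modules.
# Image convention: frames are numeric matrices indexed [row = y, col = x],
# origin at the top-left pixel (1, 1), pixel centers at integer coordinates.
# All angles are computed in a y-up mathematical frame (positive = CCW), so
# directions use atan2(-dy, dx) on stored coordinates.

#' Wrap angles into (-pi, pi]
#'
#' @param a numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Circular mean direction
#'
#' Mean direction of a set of angles; undefined when the resultant vector
#' vanishes (antipodal mass).
#'
#' @param a numeric vector of angles (radians).
#' @return mean direction in (-pi, pi].
#' @keywords internal
circular_mean <- function(a) {
  s <- mean(sin(a)); c <- mean(cos(a))
  r <- sqrt(s^2 + c^2)
  if (r < 1e-9)
    stop("undefined axis: directions have zero resultant (antipodal mass)")
  atan2(s, c)
}

# Direction (y-up) of the vector from p0 to p1 given in storage coordinates.
dir_yup <- function(p0, p1) atan2(-(p1[2] - p0[2]), p1[1] - p0[1])

#' Bilinear sampling of an image
#'
#' @param img numeric matrix `[y, x]`.
#' @param x,y query coordinates (numeric vectors, 1-based pixel centers).
#' @param fill value for queries outside the image.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 <= w - 1 & y0 <= h - 1
  # clamp edge queries that sit exactly on the last row/column
  edge <- (x0 == w & fx == 0 & y0 >= 1 & y0 <= h) |
          (y0 == h & fy == 0 & x0 >= 1 & x0 <= w)
  out <- rep(fill, length(x))
  if (any(ok)) {
    i00 <- (x0[ok] - 1) * h + y0[ok]
    v00 <- img[i00]; v10 <- img[i00 + h]
    v01 <- img[i00 + 1]; v11 <- img[i00 + h + 1]
    out[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * v00 +
               fx[ok] * (1 - fy[ok]) * v10 +
               (1 - fx[ok]) * fy[ok] * v01 +
               fx[ok] * fy[ok] * v11
  }
  rest <- edge & !ok
  if (any(rest)) out[rest] <- img[(pmin(x0[rest], w) - 1) * h + pmin(y0[rest], h)]
  out
}

# Clip to [lo, hi].
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Resample a polyline (n x 2) to (approximately) equal spacing `by` along its
# arc length, keeping the exact endpoints.
densify_polyline <- function(pts, by) {
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total == 0) return(pts[1, , drop = FALSE])
  sq <- unique(c(seq(0, total, by = by), total))
  cbind(stats::approx(s, pts[, 1], xout = sq)$y,
        stats::approx(s, pts[, 2], xout = sq)$y)
}
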