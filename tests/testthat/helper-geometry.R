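# Fixtures built in code: analytic contours, random polygons and a
# Monte-Carlo area oracle independent of the shoelace implementation.

# ellipse contour with an optional Gaussian posterior notch (indentation
# toward anterior, i.e. toward +y) centred at lateral x0
make_notched_ellipse <- function(a = 160, b = 110, n = 256, depth = 0,
                                 x0 = 0, sigma = 7, level = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  x <- a * cos(th)
  y <- b * sin(th)
  if (depth > 0)
    y <- y + depth * exp(-(x - x0)^2 / (2 * sigma^2)) * pmax(0, -y / b)
  contour_line(cbind(x, y), level = level)
}

# exactly mirror-symmetric version: right half generated, left half the
# bitwise negation of x, so symmetry holds to machine precision
make_symmetric_contour <- function(a = 160, b = 110, n_half = 128,
                                   depth = 6, sigma = 7, level = 0) {
  th <- seq(-pi / 2, pi / 2, length.out = n_half + 2L)
  th <- th[-c(1L, length(th))]              # keep poles out of the halves
  x <- a * cos(th) * ifelse(abs(th) == pi / 2, 0, 1)
  x <- abs(x)
  y <- b * sin(th)
  y <- y + depth * exp(-x^2 / (2 * sigma^2)) * pmax(0, -y / b)
  pts <- rbind(c(0, -b + depth),                       # dip bottom
               cbind(x, y),                            # right half, going up
               c(0, b),                                # anterior pole
               cbind(-rev(x), rev(y)))                 # mirrored left half
  contour_line(pts, level = level)
}

# rigid rotation of 2D points by deg around a centre
rotate_points <- function(p, deg, center = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep(sweep(p, 2L, center) %*% t(R), 2L, center, `+`)
}

# random convex polygon: convex hull of k random points
random_convex_polygon <- function(k = 25L, scale = 100) {
  p <- matrix(stats::runif(2L * k, -scale, scale), ncol = 2L)
  h <- grDevices::chull(p)
  p[h, , drop = FALSE]
}

# Monte-Carlo rejection-sampling area oracle for a convex polygon
# (ordered vertices); independent of the shoelace/hull implementation
mc_convex_area <- function(poly, n = 1e6) {
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  px <- stats::runif(n, xr[1L], xr[2L])
  py <- stats::runif(n, yr[1L], yr[2L])
  m <- nrow(poly)
  nx <- c(2:m, 1L)
  # orientation sign of the polygon
  s <- sign(sum(poly[, 1L] * poly[nx, 2L] - poly[nx, 1L] * poly[, 2L]))
  inside <- rep(TRUE, n)
  for (i in seq_len(m)) {
    j <- nx[i]
    cr <- (poly[j, 1L] - poly[i, 1L]) * (py - poly[i, 2L]) -
          (poly[j, 2L] - poly[i, 2L]) * (px - poly[i, 1L])
    inside <- inside & (s * cr >= 0)
  }
  mean(inside) * diff(xr) * diff(yr)
}

# 15-point degree-2 coronal trajectory used by the matching tests
make_c_trajectory <- function(amplitude = 20, n = 15L, height = 400) {
  z <- seq(0, height, length.out = n)
  u <- z / height
  assemble_trajectory(cbind(4 * amplitude * u * (1 - u), z))
}
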