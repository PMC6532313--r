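# Closed 2D contour lines of transverse torso sections, and the planar
# geometry primitives shared by the analysis modules.

#' Construct a transverse contour line
#'
#' A closed, ordered 2D polyline tracing the body outline in one transverse
#' plane: x is lateral (patient's right positive), y anterior-posterior
#' (anterior positive), both mm. Consecutive duplicate points are dropped.
#'
#' @param points numeric matrix with 2 columns (x, y in mm), ordered along
#'   the outline; the closing edge (last to first point) is implicit.
#' @param level z level of the plane (mm).
#' @param closed logical; contours from full transverse cuts are closed.
#' @return an object of class `contour_line`.
#' @seealso [order_contour()], [resample_contour()]
#' @export
contour_line <- function(points, level = NA_real_, closed = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("'points' must have 2 columns (x, y)")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("contour points must be finite")
  keep <- c(TRUE, rowSums(abs(diff(points))) > 1e-12)
  points <- points[keep, , drop = FALSE]
  if (closed && nrow(points) > 1L &&
      sum(abs(points[nrow(points), ] - points[1L, ])) <= 1e-12)
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 3L)
    stop("a contour line needs at least 3 distinct points")
  colnames(points) <- c("x", "y")
  structure(list(points = points, level = as.numeric(level)[1L],
                 closed = isTRUE(closed)),
            class = "contour_line")
}

#' @export
print.contour_line <- function(x, ...) {
  cat(sprintf("<contour_line> %d points at level %.1f mm (%s)\n",
              nrow(x$points), x$level,
              if (x$closed) "closed" else "open"))
  cat(sprintf("  perimeter %.1f mm, area %.0f mm^2\n",
              contour_perimeter(x), contour_area(x)))
  invisible(x)
}

# signed shoelace area of an ordered polygon (matrix n x 2)
.signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L]) / 2
}

#' Area and perimeter of an ordered contour
#'
#' `contour_area` is the absolute shoelace area of the ordered polygon —
#' order-canonical, so it is the same for any rotation of the point order.
#'
#' @param contour a [contour_line()] or an ordered 2-column point matrix.
#' @return area in mm^2 / perimeter in mm.
#' @export
contour_area <- function(contour) {
  p <- if (inherits(contour, "contour_line")) contour$points else as.matrix(contour)
  abs(.signed_area(p))
}

#' @rdname contour_area
#' @export
contour_perimeter <- function(contour) {
  p <- if (inherits(contour, "contour_line")) contour$points else as.matrix(contour)
  p <- rbind(p, p[1L, ])
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Convex-hull polygon area (Gauss's area formula)
#'
#' Computes the absolute shoelace area of the convex hull of a 2D point
#' set. This is the area measure used for the four contour sectors of the
#' rotation offset correction.
#'
#' @param points 2-column numeric matrix (mm), at least 3 non-collinear
#'   points.
#' @return area in mm^2.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
polygon_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("polygon_area needs at least 3 points, got ", nrow(points))
  h <- grDevices::chull(points[, 1L], points[, 2L])
  if (length(h) < 3L) stop("points are collinear; area undefined")
  abs(.signed_area(points[h, , drop = FALSE]))
}

# centroid of a point set
.centroid <- function(p) colMeans(p)

#' Order a scattered transverse point set into a closed contour
#'
#' Orders the 2D points of one transverse cut into a single closed polyline:
#' angular sort around the centroid, followed by a greedy nearest-neighbour
#' repair when the angular ordering leaves abnormally long edges (the slice
#' is then not star-shaped about its centroid). Orientation is normalised
#' counter-clockwise in the (x, y) plane viewed from superior.
#'
#' @param points 2-column matrix of slice points (mm).
#' @param level z level tag for the resulting contour (mm).
#' @param max_gap largest tolerated edge length (mm) in the ordered
#'   contour; a longer edge means the slice is fragmented (e.g. an arm cut
#'   by the same plane) and raises an error. Default 15 mm.
#' @return a closed [contour_line()].
#' @export
order_contour <- function(points, level = NA_real_, max_gap = 15) {
  points <- unique(as.matrix(points))
  if (nrow(points) < 3L)
    stop("need at least 3 distinct points to order a contour")
  ctr <- .centroid(points)
  rel <- sweep(points, 2L, ctr)
  if (abs(.signed_area(points[grDevices::chull(points), , drop = FALSE])) < 1e-9)
    stop("contour points are collinear")
  ord <- order(atan2(rel[, 2L], rel[, 1L]))
  p <- points[ord, , drop = FALSE]

  edge_len <- function(q) {
    qq <- rbind(q, q[1L, ])
    sqrt(rowSums(diff(qq)^2))
  }
  d <- edge_len(p)
  if (max(d) > max(3 * stats::median(d), 1)) {
    # not star-shaped about the centroid: greedy nearest-neighbour tour
    n <- nrow(p)
    used <- logical(n)
    tour <- integer(n)
    tour[1L] <- 1L
    used[1L] <- TRUE
    for (i in 2:n) {
      prev <- p[tour[i - 1L], ]
      dd <- (p[, 1L] - prev[1L])^2 + (p[, 2L] - prev[2L])^2
      dd[used] <- Inf
      tour[i] <- which.min(dd)
      used[tour[i]] <- TRUE
    }
    q <- p[tour, , drop = FALSE]
    if (max(edge_len(q)) < max(d)) p <- q
  }
  d <- edge_len(p)
  if (max(d) > max_gap)
    stop(sprintf(paste0("fragmented contour at level %.1f: gap of %.1f mm ",
                        "exceeds max_gap = %.1f mm"),
                 level, max(d), max_gap))
  if (.signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  contour_line(p, level = level, closed = TRUE)
}

#' Resample a closed contour to uniform arc length
#'
#' @param contour a closed [contour_line()].
#' @param n number of points (>= 16).
#' @return a [contour_line()] with `n` points equally spaced by arc length,
#'   starting at the original first point.
#' @export
resample_contour <- function(contour, n = 256L) {
  stopifnot(inherits(contour, "contour_line"))
  n <- as.integer(n)
  if (n < 16L) stop("resampling needs n >= 16")
  p <- rbind(contour$points, contour$points[1L, ])
  seg <- sqrt(rowSums(diff(p)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate contour with zero perimeter")
  s <- c(0, cumsum(seg))
  t <- seq(0, L, length.out = n + 1L)[seq_len(n)]
  x <- stats::approx(s, p[, 1L], xout = t, ties = "ordered")$y
  y <- stats::approx(s, p[, 2L], xout = t, ties = "ordered")$y
  contour_line(cbind(x, y), level = contour$level, closed = TRUE)
}

# arc-length resample an *open* polyline to n points (used for contour
# halves in the reflection analysis)
.resample_polyline <- function(p, n) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  t <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, p[, 1L], xout = t, ties = "ordered")$y,
        stats::approx(s, p[, 2L], xout = t, ties = "ordered")$y)
}
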