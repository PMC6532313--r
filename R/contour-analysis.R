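# Per-slice contour analysis: locate the characteristic posterior dip
# (assumed to coincide with the tip of the spinous process), fit the
# mid-sagittal reflection axis, and quantify left-right asymmetry by
# reflecting the healthy side onto the pathological side.

#' Mid-sagittal reflection axis of a transverse contour
#'
#' The line across which one body side is mirrored onto the other. It is
#' near-vertical in the transverse plane: `angle` is measured from the +y
#' (anterior) direction and must stay within +/-45 degrees; `offset` is the
#' lateral (x) position where the axis crosses the horizontal line
#' y = `y_ref` (normally the dip's y level).
#'
#' @param angle degrees from the +y direction, |angle| < 45.
#' @param offset lateral position of the axis at `y_ref` (mm).
#' @param y_ref anchor height (mm).
#' @return an object of class `reflection_axis`.
#' @export
reflection_axis <- function(angle = 0, offset = 0, y_ref = 0) {
  if (abs(angle) >= 45)
    stop("reflection axis must stay near-sagittal: |angle| < 45 degrees")
  structure(list(angle = angle, offset = offset, y_ref = y_ref),
            class = "reflection_axis")
}

# unit direction (toward anterior) and normal (toward +x) of an axis
.axis_frame <- function(axis) {
  th <- axis$angle * pi / 180
  list(a = c(axis$offset, axis$y_ref),     # anchor point
       u = c(sin(th), cos(th)),            # along-axis, anterior
       n = c(cos(th), -sin(th)))           # perpendicular, patient's right
}

#' Reflect 2D points across a reflection axis
#'
#' An exact involution: reflecting twice restores the input to machine
#' precision.
#'
#' @param points 2-column matrix (mm).
#' @param axis a [reflection_axis()].
#' @return matrix of mirrored points.
#' @export
reflect_across <- function(points, axis) {
  fr <- .axis_frame(axis)
  points <- as.matrix(points)
  w <- (points[, 1L] - fr$a[1L]) * fr$n[1L] +
       (points[, 2L] - fr$a[2L]) * fr$n[2L]
  points - 2 * outer(w, fr$n)
}

# signed lateral coordinate of points relative to the axis (+ = right)
.axis_lateral <- function(points, axis) {
  fr <- .axis_frame(axis)
  (points[, 1L] - fr$a[1L]) * fr$n[1L] + (points[, 2L] - fr$a[2L]) * fr$n[2L]
}

#' Detect the characteristic posterior dip of a contour
#'
#' Scans the posterior portion of the contour for the deepest local
#' indentation toward anterior — the surface landmark of the spinous
#' process tip. Depth is the prominence of the indentation relative to the
#' flanking posterior arch maxima. The position is refined to sub-sample
#' precision by parabolic interpolation along the arc, so it always lies on
#' the contour polyline.
#'
#' @param contour a closed, ordered [contour_line()].
#' @param search_window fraction of the total arc length, centred on the
#'   posterior-most point, searched for the dip (default 0.4: the posterior
#'   40%, avoiding anterior indentations such as the umbilicus).
#' @param depth_threshold minimal prominence (mm) for a dip to count
#'   (default 1); below it confidence is `"none"`.
#' @param clear_threshold prominence (mm) above which confidence is
#'   `"clear"` (default 3); between the thresholds it is `"weak"`.
#' @param smooth odd moving-average window (points) applied to the
#'   posterior arc before peak picking, damping scanner noise; default 3.
#' @return a `dip_estimate`: list with `position` (x, y in mm), `depth`
#'   (mm) and `confidence` (`"clear"`, `"weak"` or `"none"`).
#' @export
detect_dip <- function(contour, search_window = 0.4, depth_threshold = 1,
                       clear_threshold = 3, smooth = 3L) {
  stopifnot(inherits(contour, "contour_line"))
  if (!contour$closed) stop("dip detection needs a closed contour")
  if (search_window <= 0 || search_window > 1)
    stop("search_window must be a fraction in (0, 1]")
  ct <- resample_contour(contour, max(256L, nrow(contour$points)))
  p <- ct$points
  n <- nrow(p)
  # posterior arc: window of the closed contour centred on the min-y point
  i0 <- which.min(p[, 2L])
  half <- max(3L, floor(n * search_window / 2))
  idx <- ((i0 - half - 1L + seq_len(2L * half + 1L)) %% n) + 1L
  arc <- p[idx, , drop = FALSE]
  m <- nrow(arc)
  y <- arc[, 2L]
  smooth <- max(1L, as.integer(smooth))
  if (smooth > 1L) {
    k <- smooth %/% 2L
    ys <- stats::filter(c(y[1L] + numeric(k), y, y[m] + numeric(k)),
                        rep(1 / (2L * k + 1L), 2L * k + 1L), sides = 2)
    y <- as.numeric(ys[k + seq_len(m)])
  }
  # interior local maxima of y = indentations toward anterior
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  best <- NULL
  for (i in cand) {
    left_min <- min(y[seq_len(i)])
    right_min <- min(y[i:m])
    depth <- y[i] - max(left_min, right_min)
    if (is.null(best) || depth > best$depth) best <- list(i = i, depth = depth)
  }
  if (is.null(best) || best$depth < depth_threshold) {
    return(structure(list(position = unname(p[i0, ]), depth = 0,
                          confidence = "none"),
                     class = "dip_estimate"))
  }
  # parabolic sub-sample refinement along the arc
  i <- best$i
  frac <- 0
  if (i > 1L && i < m) {
    y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) frac <- max(-0.5, min(0.5, 0.5 * (y1 - y3) / den))
  }
  pos <- if (frac >= 0 && i < m) {
    arc[i, ] + frac * (arc[i + 1L, ] - arc[i, ])
  } else if (i > 1L) {
    arc[i, ] + frac * (arc[i, ] - arc[i - 1L, ])
  } else arc[i, ]
  structure(list(position = unname(pos), depth = best$depth,
                 confidence = if (best$depth >= clear_threshold) "clear"
                              else "weak"),
            class = "dip_estimate")
}

#' @export
print.dip_estimate <- function(x, ...) {
  cat(sprintf("<dip_estimate> at (%.2f, %.2f) mm, depth %.2f mm [%s]\n",
              x$position[1L], x$position[2L], x$depth, x$confidence))
  invisible(x)
}

# split a closed contour at its two axis crossings into (right, left) open
# halves, each ordered from the posterior crossing to the anterior crossing
.split_by_axis <- function(contour, axis) {
  p <- contour$points
  n <- nrow(p)
  w <- .axis_lateral(p, axis)
  nx <- c(2:n, 1L)
  crossing <- which(w * w[nx] < 0 | (w == 0 & w[nx] != 0))
  if (length(crossing) < 2L)
    stop("reflection axis does not cross the contour twice")
  # exact crossing points by linear interpolation
  cross_pt <- function(i) {
    j <- nx[i]
    t <- w[i] / (w[i] - w[j])
    p[i, ] + t * (p[j, ] - p[i, ])
  }
  if (length(crossing) > 2L) {
    # keep the two crossings furthest apart along the axis
    fr <- .axis_frame(axis)
    eta <- vapply(crossing, function(i) sum((cross_pt(i) - fr$a) * fr$u), 0)
    crossing <- crossing[c(which.min(eta), which.max(eta))]
  }
  crossing <- sort(crossing)
  c1 <- cross_pt(crossing[1L]); c2 <- cross_pt(crossing[2L])
  seg1_idx <- (crossing[1L] + 1L):crossing[2L]            # between crossings
  seg2_idx <- c((crossing[2L] + 1L):n, seq_len(crossing[1L]))[
    seq_len(n - (crossing[2L] - crossing[1L]))]
  h1 <- rbind(c1, p[seg1_idx, , drop = FALSE], c2)
  h2 <- rbind(c2, p[seg2_idx, , drop = FALSE], c1)
  fr <- .axis_frame(axis)
  side1 <- mean(.axis_lateral(p[seg1_idx, , drop = FALSE], axis))
  # orient both halves from posterior end to anterior end
  orient <- function(h) {
    eta_first <- sum((h[1L, ] - fr$a) * fr$u)
    eta_last <- sum((h[nrow(h), ] - fr$a) * fr$u)
    if (eta_first > eta_last) h[rev(seq_len(nrow(h))), , drop = FALSE] else h
  }
  if (side1 >= 0) list(right = orient(h1), left = orient(h2))
  else list(right = orient(h2), left = orient(h1))
}

#' Extract one body side of a contour, mirrored across the axis
#'
#' Cuts the contour at the two points where the reflection axis crosses it
#' and returns the chosen half mirrored onto the opposite side, ordered
#' from its posterior to its anterior end.
#'
#' @param contour a closed [contour_line()].
#' @param axis a [reflection_axis()].
#' @param side `"left"` or `"right"` (patient side to reflect).
#' @param reflect mirror the half (default `TRUE`); `FALSE` returns the
#'   half unmirrored.
#' @return 2-column matrix: open polyline.
#' @export
reflect_side <- function(contour, axis, side = c("left", "right"),
                         reflect = TRUE) {
  side <- match.arg(side)
  halves <- .split_by_axis(contour, axis)
  h <- halves[[side]]
  if (reflect) reflect_across(h, axis) else h
}

#' Area enclosed between two matched polylines
#'
#' The two polylines must be parameterised consistently (same number of
#' points at matching arc-length fractions). The area is the sum of the
#' absolute areas of the quadrilateral strips spanned by consecutive point
#' pairs; it is 0 exactly when the curves coincide.
#'
#' @param pathological,reflected 2-column matrices with equal row counts.
#' @return area in mm^2.
#' @export
asymmetry_area <- function(pathological, reflected) {
  a <- as.matrix(pathological); b <- as.matrix(reflected)
  if (nrow(a) != nrow(b))
    stop("polylines have mismatched parameterisation lengths: ",
         nrow(a), " vs ", nrow(b))
  if (nrow(a) < 2L) stop("need at least 2 points per polyline")
  n <- nrow(a)
  total <- 0
  for (i in seq_len(n - 1L)) {
    quad <- rbind(a[i, ], a[i + 1L, ], b[i + 1L, ], b[i, ])
    total <- total + abs(.signed_area(quad))
  }
  total
}

# squared distances from each point to the nearest segment of an open or
# closed polyline (vectorised over points x segments)
.dist2_to_polyline <- function(pts, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1L, , drop = FALSE]
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  len2 <- pmax(ex^2 + ey^2, 1e-300)
  dx <- outer(pts[, 1L], a[, 1L], "-")
  dy <- outer(pts[, 2L], a[, 2L], "-")
  t <- sweep(sweep(dx, 2L, ex, "*") + sweep(dy, 2L, ey, "*"), 2L, len2, "/")
  t <- pmin(pmax(t, 0), 1)
  px <- dx - sweep(t, 2L, ex, "*")
  py <- dy - sweep(t, 2L, ey, "*")
  apply(px^2 + py^2, 1L, min)
}

# trimmed mean squared nearest-point distance between the reflected healthy
# points and the pathological half polyline
.reflection_objective <- function(par, p, y_ref, healthy_sign, trim) {
  axis <- list(angle = par[1L], offset = par[2L], y_ref = y_ref)
  w <- .axis_lateral(p, axis)
  healthy <- p[sign(w) == healthy_sign, , drop = FALSE]
  target <- p[sign(w) == -healthy_sign, , drop = FALSE]
  if (nrow(healthy) < 5L || nrow(target) < 5L) return(1e9)
  refl <- healthy - 2 * outer(w[sign(w) == healthy_sign],
                              .axis_frame(axis)$n)
  dmin <- .dist2_to_polyline(refl, target)
  keep <- dmin <= stats::quantile(dmin, trim)
  mean(dmin[keep])
}

#' Fit the mid-sagittal reflection axis of a transverse contour
#'
#' Automates the manual axis placement of the clinical workflow: the axis
#' (angle, lateral offset) is chosen to minimise the trimmed mean squared
#' nearest-point distance between the reflected healthy half and the
#' pathological half. Trimming (default: best 70% of point distances)
#' restricts the match to the portion of the pathological side with little
#' pathological distortion, mimicking how an investigator aligns the
#' reflection where the sides still agree.
#'
#' @param contour a closed [contour_line()].
#' @param healthy_side `"auto"` (default: the side with the smaller
#'   posterior-arch hull area, i.e. without the rib hump), `"left"` or
#'   `"right"`.
#' @param init optional [reflection_axis()] starting value; default:
#'   vertical axis through the detected dip.
#' @param trim quantile of point distances kept in the objective (0-1].
#' @param n_points contour resampling used for the fit (default 180).
#' @return a `symmetry_result`: list with `axis` ([reflection_axis()]),
#'   `healthy_side`, `mismatch_area` (mm^2 between the reflected healthy
#'   half and the pathological half), `objective` (trimmed mean squared
#'   distance, mm^2) and `converged`.
#' @export
fit_reflection_axis <- function(contour, healthy_side = c("auto", "left",
                                                          "right"),
                                init = NULL, trim = 0.70, n_points = 180L) {
  stopifnot(inherits(contour, "contour_line"))
  healthy_side <- match.arg(healthy_side)
  if (trim <= 0 || trim > 1) stop("trim must be in (0, 1]")
  ct <- resample_contour(contour, n_points)
  p <- ct$points
  dip <- detect_dip(ct)
  if (is.null(init))
    init <- reflection_axis(0, dip$position[1L], y_ref = dip$position[2L])
  y_ref <- init$y_ref
  if (healthy_side == "auto") {
    post <- p[p[, 2L] <= stats::median(p[, 2L]), , drop = FALSE]
    area_side <- function(s) {
      q <- post[s * (post[, 1L] - dip$position[1L]) >= 0, , drop = FALSE]
      if (nrow(q) < 3L) return(0)
      polygon_area(q)
    }
    healthy_side <- if (area_side(-1) <= area_side(1)) "left" else "right"
  }
  hsign <- if (healthy_side == "left") -1 else 1

  obj <- function(par) .reflection_objective(par, p, y_ref, hsign, trim)
  # multi-start grid around the init, then simplex refinement
  grid <- expand.grid(angle = init$angle + seq(-10, 10, length.out = 5),
                      offset = init$offset + seq(-15, 15, length.out = 5))
  vals <- apply(grid, 1L, obj)
  starts <- grid[order(vals)[1:3], , drop = FALSE]
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[k, ]), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    if (abs(fit$par[1L]) >= 45) next  # axis must stay near-sagittal
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  converged <- TRUE
  if (is.null(best) || best$value > obj(c(init$angle, init$offset)) + 1e-12) {
    if (is.null(best)) {
      best <- list(par = c(init$angle, init$offset),
                   value = obj(c(init$angle, init$offset)))
      converged <- FALSE
    }
  }
  axis <- reflection_axis(best$par[1L], best$par[2L], y_ref = y_ref)
  halves <- .split_by_axis(ct, axis)
  healthy_refl <- reflect_across(halves[[healthy_side]], axis)
  patho <- halves[[if (healthy_side == "left") "right" else "left"]]
  nn <- max(nrow(healthy_refl), nrow(patho))
  mism <- asymmetry_area(.resample_polyline(patho, nn),
                         .resample_polyline(healthy_refl, nn))
  structure(list(axis = axis, healthy_side = healthy_side,
                 mismatch_area = mism, objective = best$value,
                 dip = dip, converged = converged),
            class = "symmetry_result")
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf(paste0("<symmetry_result> axis angle %.2f deg, offset %.2f mm",
                     " (healthy side: %s)\n"),
              x$axis$angle, x$axis$offset, x$healthy_side))
  cat(sprintf("  mismatch area %.1f mm^2, objective %.3f mm^2\n",
              x$mismatch_area, x$objective))
  invisible(x)
}
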