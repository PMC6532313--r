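# Vertebral-column trajectory: assemble per-level markers into a 3D curve,
# fit coronal-plane polynomials, compute included angles at inflexion
# points, lateral deviation and repeat-measurement spread.

#' Assemble per-level markers into a spinal trajectory
#'
#' @param markers a [marker_set()], a list of `vertebral_marker` objects
#'   (from [correct_marker()]) or a 3-column (x, y, z) matrix in mm.
#' @param source_label trajectory source tag (`"SP1"`, `"SP2"`, `"SP3"`,
#'   `"scanner"`, `"corrected"`, `"other"`).
#' @param use for marker lists: `"corrected"` (default) or `"dip"`
#'   positions.
#' @return a `spinal_trajectory`: list with `points` (n x 3 matrix, x
#'   lateral / y anterior-posterior (may be `NA`) / z level, sorted by
#'   strictly increasing z) and `source_label`.
#' @export
assemble_trajectory <- function(markers, source_label = "other",
                                use = c("corrected", "dip")) {
  use <- match.arg(use)
  if (inherits(markers, "marker_set")) {
    pts <- cbind(markers$x_mm,
                 if ("y_mm" %in% names(markers)) markers$y_mm else NA_real_,
                 markers$level_mm)
    if (source_label == "other")
      source_label <- attr(markers, "source_label")
  } else if (is.list(markers) && !is.data.frame(markers) &&
             all(vapply(markers, inherits, TRUE, "vertebral_marker"))) {
    pts <- t(vapply(markers, function(m) {
      p <- if (use == "corrected") m$corrected_position else m$dip_position
      c(p[1L], p[2L], m$level)
    }, numeric(3L)))
  } else {
    pts <- as.matrix(markers)
    if (ncol(pts) == 2L) pts <- cbind(pts[, 1L], NA_real_, pts[, 2L])
    if (ncol(pts) != 3L) stop("marker matrix must have columns x, y, z")
  }
  if (nrow(pts) < 2L) stop("a trajectory needs at least 2 markers")
  if (anyDuplicated(pts[, 3L]))
    stop("duplicate marker levels: ",
         paste(signif(unique(pts[duplicated(pts[, 3L]), 3L]), 6),
               collapse = ", "))
  pts <- pts[order(pts[, 3L]), , drop = FALSE]
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, source_label = source_label),
            class = "spinal_trajectory")
}

#' @export
print.spinal_trajectory <- function(x, ...) {
  cat(sprintf("<spinal_trajectory> %d levels, z %.0f..%.0f mm [%s]\n",
              nrow(x$points), min(x$points[, 3L]), max(x$points[, 3L]),
              x$source_label))
  invisible(x)
}

#' Fit a coronal-plane polynomial to a spinal trajectory
#'
#' Fits x(z), the coronal projection of the trajectory, with a polynomial
#' of user-chosen degree by least squares (for a polynomial model the
#' nonlinear least-squares problem is linear). Degree 1 is a straight
#' line; degrees 2, 3, 4 describe single (C-type), double (S-type) and
#' triple curved spines. Internally z is mapped to [-1, 1] for numerical
#' conditioning; coefficients are reported on that scale together with the
#' mapping.
#'
#' @param traj a `spinal_trajectory` (or [marker_set()]).
#' @param degree polynomial degree n in 1..7; needs at least n + 1 markers.
#' @return a `polynomial_fit`: list with `degree`, `coefficients`
#'   (ascending powers of the scaled level t), `z_center`, `z_scale`
#'   (t = (z - z_center)/z_scale), `z_range`, `residual_rms` (mm),
#'   `inflexion_levels` (z in mm where the second derivative vanishes
#'   inside the data range) and `n_points`.
#' @export
fit_polynomial <- function(traj, degree = 2L) {
  if (inherits(traj, "marker_set")) traj <- assemble_trajectory(traj)
  stopifnot(inherits(traj, "spinal_trajectory"))
  degree <- as.integer(degree)
  if (degree < 1L || degree > 7L) stop("degree must be in 1..7")
  x <- traj$points[, 1L]
  z <- traj$points[, 3L]
  if (length(z) <= degree)
    stop("underdetermined fit: degree ", degree, " needs more than ",
         degree, " markers, got ", length(z))
  z_center <- mean(range(z))
  z_scale <- diff(range(z)) / 2
  t <- (z - z_center) / z_scale
  X <- outer(t, 0:degree, `^`)
  co <- qr.coef(qr(X), x)
  co[is.na(co)] <- 0
  res <- x - as.vector(X %*% co)
  # inflexion levels: real roots of the second derivative inside the range
  infl <- numeric(0)
  if (degree >= 3L) {
    k <- 2:degree
    d2 <- co[k + 1L] * k * (k - 1)          # coefficients of x''(t)
    nz <- which(d2 != 0)
    if (length(nz)) {
      d2 <- d2[seq_len(max(nz))]
      r <- polyroot(d2)
      re <- Re(r[abs(Im(r)) < 1e-8])
      re <- sort(unique(re[re > -1 + 1e-9 & re < 1 - 1e-9]))
      infl <- re * z_scale + z_center
    }
  }
  structure(list(degree = degree, coefficients = as.numeric(co),
                 z_center = z_center, z_scale = z_scale,
                 z_range = range(z),
                 residual_rms = sqrt(mean(res^2)),
                 inflexion_levels = infl, n_points = length(z)),
            class = "polynomial_fit")
}

#' Evaluate a fitted coronal polynomial
#'
#' @param object a `polynomial_fit`.
#' @param z levels (mm) at which to evaluate; default: 201 points across
#'   the fitted range.
#' @param deriv 0 for x(z), 1 for dx/dz.
#' @param ... unused.
#' @return numeric vector (mm, or mm/mm slope for `deriv = 1`).
#' @export
predict.polynomial_fit <- function(object, z = NULL, deriv = 0L, ...) {
  if (is.null(z))
    z <- seq(object$z_range[1L], object$z_range[2L], length.out = 201L)
  t <- (z - object$z_center) / object$z_scale
  co <- object$coefficients
  if (deriv == 0L) {
    as.vector(outer(t, seq_along(co) - 1L, `^`) %*% co)
  } else if (deriv == 1L) {
    k <- seq_along(co) - 1L
    dc <- (co * k)[-1L]
    as.vector(outer(t, seq_along(dc) - 1L, `^`) %*% dc) / object$z_scale
  } else stop("deriv must be 0 or 1")
}

#' @export
print.polynomial_fit <- function(x, ...) {
  cat(sprintf("<polynomial_fit> degree %d on %d markers, rms %.3f mm\n",
              x$degree, x$n_points, x$residual_rms))
  if (length(x$inflexion_levels))
    cat("  inflexions at z =",
        paste(signif(x$inflexion_levels, 5), collapse = ", "), "mm\n")
  invisible(x)
}

#' Included angles at the inflexion points of a fitted trajectory
#'
#' The curvature surrogate reported alongside each fit: at the curve's
#' endpoints and at every inflexion point inside the data range, the
#' normal to the fitted coronal curve is computed; the included angles are
#' the angles between normals at adjacent knots, in degrees. Endpoints are
#' included so that C-type (degree-2) fits, which have no inflexion
#' points, still yield one total angle.
#'
#' @param fit a `polynomial_fit`.
#' @return numeric vector of angles in degrees, one per adjacent knot
#'   pair (length = number of inflexions + 1).
#' @export
included_angles <- function(fit) {
  stopifnot(inherits(fit, "polynomial_fit"))
  knots <- c(fit$z_range[1L], fit$inflexion_levels, fit$z_range[2L])
  slope <- predict(fit, z = knots, deriv = 1L)
  phi <- atan(slope)      # tangent angle; normals differ by the same angle
  abs(diff(phi)) * 180 / pi
}

#' Maximal lateral deviation and severity class of a trajectory
#'
#' The maximal perpendicular distance of the coronal curve from the
#' straight chord joining its endpoints, classified as mild (<= 10 mm),
#' moderate (10-20 mm) or strong (>= 20 mm). With
#' `baseline = "vertical"` the reference line is instead the vertical
#' through the lowest marker.
#'
#' @param obj a `polynomial_fit` or `spinal_trajectory`.
#' @param baseline `"chord"` (default) or `"vertical"`.
#' @param n_samples curve sampling density for fits (default 401).
#' @return a `deviation_summary`: list with `max_lateral_deviation` (mm)
#'   and `severity`.
#' @export
lateral_deviation <- function(obj, baseline = c("chord", "vertical"),
                              n_samples = 401L) {
  baseline <- match.arg(baseline)
  if (inherits(obj, "polynomial_fit")) {
    z <- seq(obj$z_range[1L], obj$z_range[2L], length.out = n_samples)
    x <- predict(obj, z = z)
  } else if (inherits(obj, "spinal_trajectory")) {
    x <- obj$points[, 1L]
    z <- obj$points[, 3L]
  } else stop("need a polynomial_fit or spinal_trajectory")
  if (baseline == "chord") {
    p1 <- c(x[1L], z[1L])
    p2 <- c(x[length(x)], z[length(z)])
    v <- p2 - p1
    len <- sqrt(sum(v^2))
    dev <- if (len == 0) abs(x - p1[1L]) else
      abs(v[1L] * (z - p1[2L]) - v[2L] * (x - p1[1L])) / len
  } else {
    dev <- abs(x - x[1L])
  }
  m <- max(dev)
  structure(list(max_lateral_deviation = m,
                 severity = classify_deviation(m), baseline = baseline),
            class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf("<deviation_summary> max lateral deviation %.1f mm (%s)\n",
              x$max_lateral_deviation, x$severity))
  invisible(x)
}

#' Per-level spread of repeat-measurement trajectories
#'
#' Linearly interpolates every trajectory's lateral position onto a common
#' grid over the overlapping level range and reports the standard
#' deviation across trajectories at each level. Repeat scans of the same
#' person are expected to agree to a few millimetres.
#'
#' @param trajectories list of >= 2 `spinal_trajectory` objects.
#' @param n_levels grid size (default 50).
#' @return list with `levels` (mm), `sd` (mm per level) and `max_sd` (mm).
#' @export
trajectory_spread <- function(trajectories, n_levels = 50L) {
  if (length(trajectories) < 2L)
    stop("need at least 2 trajectories to measure spread")
  stopifnot(all(vapply(trajectories, inherits, TRUE, "spinal_trajectory")))
  zr <- vapply(trajectories, function(tr) range(tr$points[, 3L]), numeric(2L))
  lo <- max(zr[1L, ]); hi <- min(zr[2L, ])
  if (lo >= hi) stop("trajectories have non-overlapping level ranges")
  grid <- seq(lo, hi, length.out = n_levels)
  X <- vapply(trajectories, function(tr) {
    stats::approx(tr$points[, 3L], tr$points[, 1L], xout = grid,
                  ties = "ordered")$y
  }, numeric(n_levels))
  sds <- apply(X, 1L, stats::sd)
  list(levels = grid, sd = sds, max_sd = max(sds))
}
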