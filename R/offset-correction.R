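# Rotation offset correction: a rotated vertebral body skews the dorsal
# rib arches without moving the spinous-process dip much, so the vertebral
# position is corrected laterally using the imbalance of four contour
# sectors around the dip.

#' Partition a transverse contour into the four offset-correction sectors
#'
#' Two cross-lines split the area surrounded by the contour: the lateral
#' separation line runs through the dip parallel to the mid-sagittal
#' (reflection) axis; the anterior-posterior separation line is
#' perpendicular to it at a distance `d` anterior of the dip. This yields
#' two anterior sectors (A on the patient's right, B left) and two
#' posterior sectors (C right, D left). Each sector's area is the convex
#' hull of its contour points (plus the cross-line intersection points),
#' evaluated with Gauss's area formula. Points exactly on a separation
#' line are assigned to the +x / anterior sector.
#'
#' `R_omega` is the remaining width between the dip and the intersection of
#' the anterior-posterior separation line with the body contour, measured
#' on the side toward which the sector imbalance points.
#'
#' @param contour a closed [contour_line()].
#' @param dip dip position: a `dip_estimate` or an (x, y) vector (mm).
#' @param axis a [reflection_axis()]; default: vertical axis through the
#'   dip.
#' @param d anterior-posterior separation distance from the dip (mm).
#'   Estimated from transverse CT sections of non-scoliotic persons; the
#'   vertebral-body-to-skin distance is close to constant within a person,
#'   so a single `d` per subject is used (default 50 mm).
#' @return a `sector_partition`: list with areas `A`, `B`, `C`, `D`
#'   (mm^2), `R_omega` (mm), `d`, `dip`, `imbalance` (the dimensionless
#'   sector-imbalance sum) and `axis`.
#' @export
partition_sectors <- function(contour, dip, axis = NULL, d = 50) {
  stopifnot(inherits(contour, "contour_line"))
  if (inherits(dip, "dip_estimate")) dip <- dip$position
  dip <- as.numeric(dip)
  if (d <= 0) stop("separation distance d must be > 0")
  if (is.null(axis)) axis <- reflection_axis(0, dip[1L], y_ref = dip[2L])
  fr <- .axis_frame(axis)
  p <- contour$points
  rel <- cbind(p[, 1L] - dip[1L], p[, 2L] - dip[2L])
  xi <- rel[, 1L] * fr$n[1L] + rel[, 2L] * fr$n[2L]   # lateral, + = right
  eta <- rel[, 1L] * fr$u[1L] + rel[, 2L] * fr$u[2L]  # anterior of dip
  if (d >= max(eta))
    stop("separation distance d = ", d,
         " exceeds the contour's anterior extent at the dip")

  # crossings of the closed polyline with each separation line
  crossings <- function(val) {
    n <- length(val)
    nx <- c(2:n, 1L)
    idx <- which(val * val[nx] < 0 | (val == 0))
    out <- matrix(0, nrow = 0L, ncol = 2L)
    for (i in idx) {
      j <- nx[i]
      if (val[i] == 0) {
        out <- rbind(out, cbind(xi[i], eta[i]))
      } else if (val[i] * val[j] < 0) {
        t <- val[i] / (val[i] - val[j])
        out <- rbind(out, cbind(xi[i] + t * (xi[j] - xi[i]),
                                eta[i] + t * (eta[j] - eta[i])))
      }
    }
    out
  }
  lat_cross <- crossings(xi)        # on the lateral line (xi = 0)
  ap_cross <- crossings(eta - d)    # on the anterior-posterior line
  if (nrow(ap_cross) < 2L)
    stop("anterior-posterior separation line does not cross the contour")
  ap_right <- ap_cross[which.max(ap_cross[, 1L]), ]
  ap_left <- ap_cross[which.min(ap_cross[, 1L]), ]

  pts <- cbind(xi, eta)
  corner <- c(0, d)
  sector_pts <- function(sx, sy) {
    sel <- if (sx > 0) xi >= 0 else xi < 0
    sel <- sel & (if (sy > 0) eta >= d else eta < d)
    extra <- rbind(corner,
                   if (sx > 0) ap_right else ap_left,
                   lat_cross[(if (sy > 0) lat_cross[, 2L] >= d
                              else lat_cross[, 2L] < d), , drop = FALSE])
    rbind(pts[sel, , drop = FALSE], extra)
  }
  hull_area <- function(q, name) {
    if (nrow(q) < 3L)
      stop("degenerate sector ", name, ": fewer than 3 points")
    polygon_area(q)
  }
  A <- hull_area(sector_pts(+1, +1), "A")
  B <- hull_area(sector_pts(-1, +1), "B")
  C <- hull_area(sector_pts(+1, -1), "C")
  D <- hull_area(sector_pts(-1, -1), "D")
  if (A + B == 0 || C + D == 0)
    stop("degenerate sector areas: A+B or C+D is zero")
  imb <- (A - B) / (A + B) + (C - D) / (C + D)
  R_omega <- abs(if (imb >= 0) ap_right[1L] else ap_left[1L])
  structure(list(A = A, B = B, C = C, D = D, R_omega = R_omega, d = d,
                 dip = dip, imbalance = imb, axis = axis),
            class = "sector_partition")
}

#' @export
print.sector_partition <- function(x, ...) {
  cat(sprintf(paste0("<sector_partition> A %.0f  B %.0f  C %.0f  D %.0f",
                     " mm^2;  R_omega %.1f mm, d %.0f mm\n"),
              x$A, x$B, x$C, x$D, x$R_omega, x$d))
  invisible(x)
}

#' Lateral offset correction from the sector imbalance
#'
#' The empirical lateral correction applied to the dip position:
#' \deqn{x_{off} = \left(\frac{A-B}{A+B} + \frac{C-D}{C+D}\right) R_\omega}
#' It is 0 for a symmetric contour and positive when the vertebral body is
#' rotated toward the patient's right. The printed form of the formula is
#' ambiguous about whether \eqn{R_\omega} scales both imbalance terms or
#' only the posterior one; the default scales the sum, and
#' `grouping = "second-term"` selects the alternative reading
#' \eqn{(A-B)/(A+B) + R_\omega (C-D)/(C+D)} for sensitivity analysis.
#'
#' @param partition a [partition_sectors()] result.
#' @param grouping `"sum"` (default) or `"second-term"`.
#' @return signed lateral offset `x_off` (mm).
#' @export
compute_offset <- function(partition, grouping = c("sum", "second-term")) {
  stopifnot(inherits(partition, "sector_partition"))
  grouping <- match.arg(grouping)
  if (partition$A + partition$B == 0 || partition$C + partition$D == 0)
    stop("degenerate sector areas: A+B or C+D is zero")
  with(partition, {
    t1 <- (A - B) / (A + B)
    t2 <- (C - D) / (C + D)
    if (grouping == "sum") (t1 + t2) * R_omega else t1 + t2 * R_omega
  })
}

#' Build a corrected vertebral marker for one level
#'
#' The corrected lateral position is the dip shifted by `x_off`; the raw
#' dip is retained so that dip-based (SP2-like) and corrected trajectories
#' stay distinguishable downstream.
#'
#' @param dip a `dip_estimate` or (x, y) position (mm).
#' @param x_off lateral offset (mm), from [compute_offset()].
#' @param level slice height z (mm).
#' @return a `vertebral_marker`: list with `level`, `dip_position`,
#'   `x_off`, `corrected_position`.
#' @export
correct_marker <- function(dip, x_off, level) {
  if (inherits(dip, "dip_estimate")) dip <- dip$position
  dip <- unname(as.numeric(dip))
  structure(list(level = as.numeric(level)[1L], dip_position = dip,
                 x_off = as.numeric(x_off)[1L],
                 corrected_position = c(dip[1L] + x_off, dip[2L])),
            class = "vertebral_marker")
}
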