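# Transverse sectional planes: cut the torso surface at chosen levels along
# the vertical body axis; each cut yields the point set of one contour line.

#' Plan transverse slice levels
#'
#' Equally spaced levels along the vertical torso axis. Ten to fifteen
#' levels at regular intervals over the lumbar and thoracic section are
#' usually enough to capture the vertebral-column trajectory; severe
#' curvatures profit from more.
#'
#' @param z_min,z_max vertical extent to cover (mm), `z_min < z_max`.
#' @param count number of levels (>= 2), both ends included.
#' @param thickness slab half-width (mm) used when slicing raw point
#'   clouds; ignored for triangle meshes (exact plane cuts).
#' @return a `slice_plan`: list with `levels` (mm, ascending) and
#'   `thickness`.
#' @export
#' @examples
#' plan_levels(0, 100, 11)$levels   # 0, 10, ..., 100
plan_levels <- function(z_min, z_max, count = 15L, thickness = 2) {
  if (!(z_min < z_max)) stop("z_min must be < z_max")
  count <- as.integer(count)
  if (count < 2L) stop("need at least 2 levels")
  if (thickness <= 0) stop("thickness must be > 0")
  structure(list(levels = seq(z_min, z_max, length.out = count),
                 thickness = thickness),
            class = "slice_plan")
}

#' Extract the point set of one transverse cut
#'
#' For a triangle mesh, the cut is the exact intersection of mesh edges
#' with the plane z = `level`, so every returned point lies exactly in the
#' plane. For a raw point cloud (no faces), all vertices within the slab
#' `level` +/- `thickness` are projected onto the plane.
#'
#' @param scan a [surface_scan()].
#' @param level plane height z (mm).
#' @param thickness slab half-width (mm) for point-cloud scans; default 2.
#' @return 2-column matrix of (x, y) points (mm), unordered; pass to
#'   [order_contour()].
#' @export
extract_slice <- function(scan, level, thickness = 2) {
  stopifnot(inherits(scan, "surface_scan"))
  v <- scan$vertices
  if (!is.null(scan$faces) && nrow(scan$faces) > 0L) {
    f <- scan$faces
    pts <- vector("list", 3L)
    pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
    for (k in 1:3) {
      i <- f[, pairs[[k]][1L]]
      j <- f[, pairs[[k]][2L]]
      z1 <- v[i, 3L]; z2 <- v[j, 3L]
      cross <- (z1 - level) * (z2 - level) < 0
      if (any(cross)) {
        t <- (level - z1[cross]) / (z2[cross] - z1[cross])
        pts[[k]] <- cbind(v[i[cross], 1L] + t * (v[j[cross], 1L] - v[i[cross], 1L]),
                          v[i[cross], 2L] + t * (v[j[cross], 2L] - v[i[cross], 2L]))
      }
    }
    on_plane <- abs(v[, 3L] - level) < 1e-12
    out <- rbind(do.call(rbind, pts),
                 if (any(on_plane)) v[on_plane, 1:2, drop = FALSE])
    if (is.null(out) || nrow(out) == 0L)
      stop(sprintf("empty slice: plane z = %.1f mm does not cut the mesh",
                   level))
    out <- unique(round(out, 9L))
  } else {
    if (thickness <= 0) stop("thickness must be > 0")
    sel <- abs(v[, 3L] - level) <= thickness
    out <- v[sel, 1:2, drop = FALSE]
  }
  if (nrow(out) < 8L)
    stop(sprintf("empty slice: %d point(s) at level z = %.1f mm (need >= 8)",
                 nrow(out), level))
  colnames(out) <- c("x", "y")
  out
}

#' Slice a scan into an ordered contour stack
#'
#' Convenience wrapper: [extract_slice()] + [order_contour()] +
#' [resample_contour()] at every level of a plan. Fragmented or empty
#' slices are skipped with a warning rather than aborting the stack.
#'
#' @param scan a [surface_scan()].
#' @param plan a [plan_levels()] plan.
#' @param n_points points per resampled contour (default 256).
#' @param max_gap see [order_contour()].
#' @return named list of [contour_line()] objects (names: level in mm).
#' @export
slice_scan <- function(scan, plan, n_points = 256L, max_gap = 15) {
  stopifnot(inherits(plan, "slice_plan"))
  out <- list()
  for (lv in plan$levels) {
    ct <- tryCatch({
      pts <- extract_slice(scan, lv, plan$thickness)
      resample_contour(order_contour(pts, level = lv, max_gap = max_gap),
                       n_points)
    }, error = function(e) {
      warning("skipping level ", signif(lv, 6), ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(ct)) out[[as.character(signif(lv, 10))]] <- ct
  }
  out
}
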