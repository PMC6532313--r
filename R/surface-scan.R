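#' Construct a torso surface scan
#'
#' A `surface_scan` holds a torso surface as a vertex matrix (and optionally
#' a triangle index matrix) in millimetres, using the RAS convention:
#' x toward the patient's right, y anterior, z superior. All downstream
#' slicing and contour analysis assumes this frame, so that a positive
#' lateral offset means "toward the patient's right side".
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm), one row per
#'   vertex. At least 4 vertices are required.
#' @param faces optional integer matrix with 3 columns of 1-based vertex
#'   indices, one row per triangle.
#' @param provenance free-text source tag carried through reports.
#' @return an object of class `surface_scan` with elements `vertices`,
#'   `faces` (or `NULL`) and `provenance`.
#' @seealso [read_surface()], [apply_mask()], [extract_slice()]
#' @export
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
#' surface_scan(v, f)
surface_scan <- function(vertices, faces = NULL, provenance = "unknown") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L)
    stop("'vertices' must have 3 columns (x, y, z in mm)")
  storage.mode(vertices) <- "double"
  if (nrow(vertices) < 4L)
    stop("a surface scan needs at least 4 vertices, got ", nrow(vertices))
  if (!all(is.finite(vertices)))
    stop("all vertex coordinates must be finite")
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3L)
      stop("'faces' must have 3 columns of vertex indices")
    storage.mode(faces) <- "integer"
    if (nrow(faces) > 0L &&
        (min(faces) < 1L || max(faces) > nrow(vertices)))
      stop("face indices must lie in 1..", nrow(vertices))
    dimnames(faces) <- NULL
  }
  rownames(vertices) <- NULL
  colnames(vertices) <- c("x", "y", "z")
  structure(
    list(vertices = vertices, faces = faces,
         provenance = as.character(provenance)[1L]),
    class = "surface_scan"
  )
}

#' @export
print.surface_scan <- function(x, ...) {
  cat("<surface_scan> ", nrow(x$vertices), " vertices",
      if (!is.null(x$faces)) paste0(", ", nrow(x$faces), " faces"),
      "\n", sep = "")
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Declarative mask regions
#'
#' Axis-aligned box marking vertices to *exclude* from analysis, standing in
#' for interactive masking of, e.g., arms or a waist band. Bounds may be
#' `-Inf`/`Inf` to leave an axis unconstrained.
#'
#' @param xlim,ylim,zlim length-2 numeric bounds (mm), min < max.
#' @return an object of class `mask_region`.
#' @export
#' @examples
#' mask_box(zlim = c(-Inf, 100))  # drop everything below z = 100 mm
mask_box <- function(xlim = c(-Inf, Inf), ylim = c(-Inf, Inf),
                     zlim = c(-Inf, Inf)) {
  bounds <- rbind(x = xlim, y = ylim, z = zlim)
  if (ncol(bounds) != 2L || any(bounds[, 1] >= bounds[, 2]))
    stop("each mask axis needs bounds with min < max")
  structure(list(bounds = bounds), class = "mask_region")
}

#' Remove masked vertices from a scan
#'
#' Vertices falling inside the mask region are removed; faces referencing a
#' removed vertex are dropped. The input scan is not modified. Masking is
#' idempotent: applying the same mask twice equals applying it once.
#'
#' @param scan a [surface_scan()].
#' @param mask a [mask_box()].
#' @return a new `surface_scan` containing exactly the vertices outside the
#'   mask.
#' @export
apply_mask <- function(scan, mask) {
  stopifnot(inherits(scan, "surface_scan"), inherits(mask, "mask_region"))
  b <- mask$bounds
  v <- scan$vertices
  inside <- v[, 1] >= b[1, 1] & v[, 1] <= b[1, 2] &
            v[, 2] >= b[2, 1] & v[, 2] <= b[2, 2] &
            v[, 3] >= b[3, 1] & v[, 3] <= b[3, 2]
  keep <- which(!inside)
  if (length(keep) == 0L)
    stop("mask removes every vertex of the scan")
  new_index <- integer(nrow(v))
  new_index[keep] <- seq_along(keep)
  faces <- scan$faces
  if (!is.null(faces)) {
    ok <- !inside[faces[, 1]] & !inside[faces[, 2]] & !inside[faces[, 3]]
    faces <- faces[ok, , drop = FALSE]
    faces[] <- new_index[faces]
  }
  if (length(keep) < 4L)
    stop("masking left fewer than 4 vertices")
  surface_scan(v[keep, , drop = FALSE], faces,
               provenance = scan$provenance)
}
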