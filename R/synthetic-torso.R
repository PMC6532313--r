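# Parametric synthetic torso with a known embedded spine: superellipse
# cross-sections, a Gaussian posterior dip at the spinous-process
# position, and a rotation-driven unilateral posterior bump (rib hump)
# with contralateral anterior flattening. Every generated quantity has an
# analytic ground truth, so each pipeline stage can be validated without
# patient data.

# evaluate polynomial coefficients (ascending powers) at u
.polyval <- function(coef, u) {
  as.vector(outer(u, seq_along(coef) - 1L, `^`) %*% coef)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic torso
#'
#' Defines the stated world of the generator. The cross-section is a
#' superellipse whose half-widths swell smoothly toward mid-torso. The
#' embedded spinous-process line (the contour centre, where the dip sits)
#' is a polynomial in the normalised height u = z/height. Vertebral
#' rotation (parabolic profile with apex at mid-height, or any user
#' function of z) drives a posterior bump on the side toward which the
#' body rotates plus an equal anterior flattening on the opposite side —
#' asymmetry of the dorsal arches without moving the dip — and shifts
#' the vertebral body laterally away from the dip by
#' `delta_skin * tan(rotation)`.
#'
#' @param height torso height (mm).
#' @param a,b lateral / anterior-posterior half-widths at mid-torso (mm).
#' @param exponent superellipse exponent (2 = ellipse; 2.5 gives a
#'   torso-like roundness).
#' @param spine_coef coefficients (ascending powers of u = z/height) of
#'   the spinous-process-line lateral position x(u) in mm; the
#'   vertebral-body line is this plus the rotation-induced shift.
#' @param rotation_max apex vertebral rotation (degrees, parabolic profile
#'   `rotation_max * 4u(1-u)`), or a `function(z)` returning degrees.
#' @param dip_depth posterior dip depth (mm).
#' @param dip_width Gaussian sigma of the dip (mm).
#' @param hump_scale rib-hump amplitude per unit `sin(rotation)` (mm);
#'   the default is calibrated so that the sector-area offset correction
#'   approximately recovers the true lateral body-dip shift.
#' @param delta_skin vertebral-body-to-back-skin distance (mm).
#' @param noise_sigma Gaussian vertex noise of the scanner (mm).
#' @param seed RNG seed for the noise.
#' @param levels number of ground-truth/analysis levels (spread over the
#'   central 70% of the height).
#' @param n_rings,n_ring_points mesh resolution of [generate_torso()].
#' @return an object of class `torso_spec`.
#' @export
torso_spec <- function(height = 450, a = 160, b = 110, exponent = 2.5,
                       spine_coef = c(0, 0, 0), rotation_max = 0,
                       dip_depth = 6, dip_width = 5, hump_scale = 80,
                       delta_skin = 50, noise_sigma = 0.5, seed = 1L,
                       levels = 15L, n_rings = 80L, n_ring_points = 128L) {
  if (height <= 0 || a <= 0 || b <= 0) stop("height, a, b must be > 0")
  if (min(a, b) <= dip_depth)
    stop("half-widths must exceed the dip depth")
  if (is.numeric(rotation_max) && abs(rotation_max) > 30)
    stop("|rotation| must be <= 30 degrees")
  structure(list(height = height, a = a, b = b, exponent = exponent,
                 spine_coef = spine_coef, rotation_max = rotation_max,
                 dip_depth = dip_depth, dip_width = dip_width,
                 hump_scale = hump_scale, delta_skin = delta_skin,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 levels = as.integer(levels), n_rings = as.integer(n_rings),
                 n_ring_points = as.integer(n_ring_points)),
            class = "torso_spec")
}

#' Preset synthetic torsos
#'
#' `"straight"`: no curve, no rotation. `"c-mild"`: C-curve of 8 mm
#' amplitude, 5 degrees apex rotation. `"c-strong"`: 40 mm amplitude,
#' 20 degrees. `"s-curve"`: S-shaped double curve of +/-12 mm, 10
#' degrees.
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @param ... overrides passed on to [torso_spec()].
#' @return a `torso_spec`.
#' @export
preset_torso <- function(preset = c("straight", "c-mild", "c-strong",
                                    "s-curve"), seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "straight" = list(spine_coef = c(0, 0, 0), rotation_max = 0),
    # parabola 4*A*u*(1-u) has apex amplitude A at mid-height
    "c-mild"   = list(spine_coef = c(0, 32, -32), rotation_max = 5),
    "c-strong" = list(spine_coef = c(0, 160, -160), rotation_max = 20),
    # cubic through 0 at u = 0, 1/2, 1 with extrema ~ +/-12 mm
    "s-curve"  = list(spine_coef = 12 / 0.0962 * c(0, 1, -3, 2),
                      rotation_max = 10)
  )
  do.call(torso_spec, c(args, list(seed = seed), list(...)))
}

# rotation (degrees) of the vertebral body at height z
.rotation_at <- function(spec, z) {
  u <- z / spec$height
  if (is.function(spec$rotation_max)) spec$rotation_max(z)
  else spec$rotation_max * 4 * u * (1 - u)
}

# smooth barrel shape factor for the half-widths
.shape_factor <- function(u) 0.85 + 0.15 * sin(pi * pmin(pmax(u, 0), 1))

# analytic cross-section outline at height z (no noise); n points
.torso_ring <- function(spec, z, n) {
  u <- z / spec$height
  s <- .shape_factor(u)
  a_z <- spec$a * s
  b_z <- spec$b * s
  x_sp <- .polyval(spec$spine_coef, u)   # spinous-process / contour centre
  rot <- .rotation_at(spec, z)
  m <- spec$exponent
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  xr <- a_z * sign(cos(th)) * abs(cos(th))^(2 / m)
  y <- b_z * sign(sin(th)) * abs(sin(th))^(2 / m)
  w_post <- pmax(0, -y / b_z)
  w_ant <- pmax(0, y / b_z)
  # spinous-process dip: indentation toward anterior at the centre — axial
  # rotation skews the dorsal arches but barely moves the dip itself
  y <- y + spec$dip_depth * exp(-xr^2 / (2 * spec$dip_width^2)) * w_post
  # rib hump on the rotation side + contralateral anterior flattening,
  # amplitude ~ sin(rotation)
  h <- spec$hump_scale * sin(abs(rot) * pi / 180)
  if (h > 0) {
    side <- sign(rot)
    x_h <- side * 0.6 * a_z
    s_h <- 0.13 * a_z
    y <- y - h * exp(-(xr - x_h)^2 / (2 * s_h^2)) * w_post
    y <- y - h * exp(-(xr + x_h)^2 / (2 * s_h^2)) * w_ant
  }
  cbind(x = x_sp + xr, y = y)
}

#' Generate one synthetic transverse contour with its ground truth
#'
#' @param spec a [torso_spec()].
#' @param level height z (mm) in [0, height].
#' @param n_points contour points (default 256).
#' @return list with `contour` (a noise-free [contour_line()]) and
#'   `truth`: `dip` (x, y), `vertebral_body` (x, y), `rotation_deg`,
#'   `delta_mm`, `area_mm2`.
#' @export
generate_contour <- function(spec, level, n_points = 256L) {
  stopifnot(inherits(spec, "torso_spec"))
  if (level < 0 || level > spec$height)
    stop("level must lie in [0, ", spec$height, "] mm")
  ring <- .torso_ring(spec, level, n_points)
  ct <- contour_line(ring, level = level, closed = TRUE)
  u <- level / spec$height
  x_dip <- .polyval(spec$spine_coef, u)
  rot <- .rotation_at(spec, level)
  # the vertebral body sits delta_skin anterior of the dip and rotates
  # toward the rotation side: lateral shift delta_skin * tan(rotation)
  x_vb <- x_dip + spec$delta_skin * tan(rot * pi / 180)
  # posterior skin height at a given lateral position, by interpolation on
  # a dense ring
  dense <- .torso_ring(spec, level, 2048L)
  post <- dense[dense[, 2L] < 0, , drop = FALSE]
  post <- post[order(post[, 1L]), , drop = FALSE]
  y_at <- function(xq) stats::approx(post[, 1L], post[, 2L], xout = xq,
                                     ties = "ordered")$y
  dip <- c(x_dip, y_at(x_dip))
  vb <- c(x_vb, y_at(x_vb) + spec$delta_skin)
  list(contour = ct,
       truth = list(dip = dip, vertebral_body = vb, rotation_deg = rot,
                    delta_mm = spec$delta_skin,
                    area_mm2 = abs(.signed_area(dense))))
}

#' Generate a synthetic torso mesh with ground truth
#'
#' Stacks analytic cross-section rings into a closed triangle mesh, adds
#' Gaussian vertex noise with the spec's seed (deterministic: the same
#' spec and seed give a bit-identical mesh), and returns the per-level
#' ground truth at `spec$levels` analysis levels spread over the central
#' 70% of the height.
#'
#' @param spec a [torso_spec()].
#' @return list with `scan` (a [surface_scan()]) and `truth`: `levels`
#'   (mm), `spine` (n x 3 matrix of vertebral-body positions),
#'   `dip` (n x 3), `rotation_deg`, `delta_mm`, `area_mm2`, and the
#'   generating `spec`.
#' @export
generate_torso <- function(spec) {
  stopifnot(inherits(spec, "torso_spec"))
  nr <- spec$n_rings
  np <- spec$n_ring_points
  zs <- seq(0, spec$height, length.out = nr)
  verts <- do.call(rbind, lapply(zs, function(z)
    cbind(.torso_ring(spec, z, np), z)))
  # side triangles between consecutive rings
  k <- seq_len(np)
  kn <- c(2:np, 1L)
  faces <- do.call(rbind, lapply(seq_len(nr - 1L), function(i) {
    lo <- (i - 1L) * np
    hi <- i * np
    rbind(cbind(lo + k, lo + kn, hi + k),
          cbind(lo + kn, hi + kn, hi + k))
  }))
  # cap fans through ring centroids
  c_bot <- nrow(verts) + 1L
  c_top <- nrow(verts) + 2L
  verts <- rbind(verts,
                 c(colMeans(verts[k, 1:2, drop = FALSE]), 0),
                 c(colMeans(verts[(nr - 1L) * np + k, 1:2, drop = FALSE]),
                   spec$height))
  faces <- rbind(faces,
                 cbind(k, c_bot, kn),
                 cbind((nr - 1L) * np + kn, c_top, (nr - 1L) * np + k))
  if (spec$noise_sigma > 0)
    verts <- verts + .with_seed(spec$seed,
      matrix(stats::rnorm(length(verts), sd = spec$noise_sigma),
             nrow = nrow(verts)))
  scan <- surface_scan(verts, faces,
                       provenance = sprintf("synthetic torso (seed %d)",
                                            spec$seed))
  lv <- seq(0.15, 0.85, length.out = spec$levels) * spec$height
  gt <- lapply(lv, function(z) generate_contour(spec, z)$truth)
  truth <- list(
    levels = lv,
    spine = cbind(t(vapply(gt, `[[`, numeric(2L), "vertebral_body")), lv),
    dip = cbind(t(vapply(gt, `[[`, numeric(2L), "dip")), lv),
    rotation_deg = vapply(gt, `[[`, 0, "rotation_deg"),
    delta_mm = vapply(gt, `[[`, 0, "delta_mm"),
    area_mm2 = vapply(gt, `[[`, 0, "area_mm2"),
    spec = spec
  )
  colnames(truth$spine) <- colnames(truth$dip) <- c("x", "y", "z")
  list(scan = scan, truth = truth)
}
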