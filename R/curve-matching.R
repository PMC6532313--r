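# Rigid matching of two coronal spinal trajectories: unconstrained
# translation plus a rotation about the moving curve's centre point,
# bounded to (-45, +45) degrees so a curve cannot be matched upside-down.
# The residual-based optimality value quantifies the agreement.

# sample a curve's coronal projection at n points uniform in normalized
# level; returns an n x 2 matrix of (x, z)
.coronal_samples <- function(obj, n) {
  if (inherits(obj, "polynomial_fit")) {
    z <- seq(obj$z_range[1L], obj$z_range[2L], length.out = n)
    return(cbind(predict(obj, z = z), z))
  }
  if (inherits(obj, "marker_set")) obj <- assemble_trajectory(obj)
  if (!inherits(obj, "spinal_trajectory"))
    stop("need a spinal_trajectory, marker_set or polynomial_fit")
  p <- obj$points[order(obj$points[, 3L]), , drop = FALSE]
  z <- seq(p[1L, 3L], p[nrow(p), 3L], length.out = n)
  x <- stats::approx(p[, 3L], p[, 1L], xout = z, ties = "ordered")$y
  cbind(x, z)
}

.rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Rigidly match two coronal spinal trajectories
#'
#' Both curves are resampled to `n_samples` points uniformly spaced in
#' normalised level and matched point-to-point (trajectories share the
#' level axis, so equal-level correspondence avoids degenerate sliding).
#' The moving curve is rotated by `alpha` about its centre point (the
#' sampled point at the middle of its level range) and translated; the
#' optimal translation for a given rotation is computed in closed form,
#' and the rotation is optimised by a bounded multi-start search over
#' alpha in (-45, +45) degrees. The optimality value is the minimised
#' mean squared point distance: 0 for a perfect match, growing with the
#' mismatch between the curves.
#'
#' @param moving,fixed `spinal_trajectory`, [marker_set()] or
#'   `polynomial_fit` objects.
#' @param n_samples points per curve (>= 10, default 50).
#' @return a `match_result`: list with `translation` (tx lateral, ty
#'   vertical, mm) and `rotation_alpha` (degrees) — the detected
#'   displacement and rotation of the moving curve relative to the fixed
#'   one (the alignment applies their inverse) — plus `optimality`
#'   (mm^2), `residuals` (per-point distances, mm), `center` (rotation
#'   centre of the moving curve) and `n_samples`.
#' @export
match_curves <- function(moving, fixed, n_samples = 50L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 10L) stop("n_samples must be >= 10")
  P <- .coronal_samples(moving, n_samples)
  Q <- .coronal_samples(fixed, n_samples)
  ctr <- P[(n_samples + 1L) %/% 2L, ]
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  # profiled objective: translation eliminated in closed form
  obj <- function(alpha) {
    R <- .rot2(alpha)
    mean(rowSums((Pc %*% t(R) - Qc)^2))
  }
  best <- NULL
  for (a0 in c(-30, 0, 30)) {
    fit <- stats::optim(a0, obj, method = "L-BFGS-B",
                        lower = -45, upper = 45,
                        control = list(factr = 1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  align_alpha <- as.numeric(best$par)
  R <- .rot2(align_alpha)
  moved <- sweep(P, 2L, ctr) %*% t(R)
  moved <- sweep(moved, 2L, ctr, `+`)
  # displacement of the (rotation-corrected) moving curve relative to the
  # fixed curve; the alignment subtracts it
  tr <- colMeans(moved) - colMeans(Q)
  moved <- sweep(moved, 2L, tr)
  resid <- sqrt(rowSums((moved - Q)^2))
  structure(list(translation = c(tx = tr[1L], ty = tr[2L]),
                 rotation_alpha = -align_alpha,
                 optimality = mean(resid^2), residuals = resid,
                 center = ctr, n_samples = n_samples),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(paste0("<match_result> translation (%.2f, %.2f) mm, ",
                     "rotation %.2f deg\n"),
              x$translation[1L], x$translation[2L], x$rotation_alpha))
  cat(sprintf("  optimality %.4g mm^2 (mean squared residual, %d samples)\n",
              x$optimality, x$n_samples))
  invisible(x)
}

#' Mean optimality per severity group
#'
#' Summarises a set of match results by severity group: mean optimality
#' (and its log10) per group, in the given group order. A gradual
#' increase of the mean optimality with severity indicates an increasing
#' mismatch between dip-derived and vertebral-body-derived trajectories.
#'
#' @param matches list of `match_result` objects (or numeric optimality
#'   values).
#' @param groups character/factor of the same length assigning each match
#'   to a severity group.
#' @return data frame with columns `group`, `n`, `mean_optimality`,
#'   `log10_mean_optimality`. Empty groups are dropped with a warning.
#' @export
optimality_table <- function(matches, groups) {
  vals <- vapply(matches, function(m) {
    if (inherits(m, "match_result")) m$optimality else as.numeric(m)
  }, 0)
  if (length(vals) != length(groups))
    stop("'matches' and 'groups' lengths differ")
  groups <- if (is.factor(groups)) groups else factor(groups,
                                                      levels = unique(groups))
  empty <- setdiff(levels(groups), as.character(unique(groups)))
  if (length(empty))
    warning("empty severity group(s) omitted: ",
            paste(empty, collapse = ", "))
  mn <- tapply(vals, groups, mean)
  mn <- mn[!is.na(mn)]
  data.frame(group = names(mn), n = as.vector(table(groups)[names(mn)]),
             mean_optimality = as.vector(mn),
             log10_mean_optimality = log10(as.vector(mn)),
             row.names = NULL)
}
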