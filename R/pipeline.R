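# End-to-end orchestration: scan (or contour stack) -> per-slice dip,
# reflection axis, sector areas, offset correction -> trajectory ->
# polynomial fit, included angles, deviation class -> optional curve
# match against a second trajectory -> JSON report + trajectory CSV.

#' Analyse a torso scan or contour stack
#'
#' Runs the per-slice contour analysis at every level and assembles the
#' vertebral-column trajectory. Slices that fail (fragmented contour, no
#' dip, degenerate sectors) are flagged and skipped; the analysis
#' continues as long as at least two usable levels remain.
#'
#' @param x a [surface_scan()] or a list of [contour_line()] objects.
#' @param levels slice levels (mm). Default for scans: `n_levels` levels
#'   over the central 70% of the z range (avoiding shoulders and pelvis
#'   caps). Ignored for contour stacks (their own levels are used).
#' @param n_levels number of default levels (15).
#' @param thickness slab half-width for point-cloud slicing (mm).
#' @param d sector separation distance (mm), see [partition_sectors()].
#' @param trim trimming quantile of the reflection-axis fit.
#' @param healthy_side `"auto"`, `"left"` or `"right"`.
#' @param degree polynomial degree for the trajectory fit.
#' @param grouping offset-formula grouping, see [compute_offset()].
#' @param n_points contour resampling (default 256).
#' @param max_gap fragmentation threshold (mm) for [order_contour()].
#' @return a `scan_analysis`: list with `slices` (per-level results),
#'   `markers`, `trajectory_dip` (raw dip positions, SP2-like),
#'   `trajectory_corrected`, `fit`, `included_angles`, `deviation`,
#'   `params` and `log` (automated decisions, one entry per event).
#' @export
analyze_scan <- function(x, levels = NULL, n_levels = 15L, thickness = 2,
                         d = 50, trim = 0.70,
                         healthy_side = c("auto", "left", "right"),
                         degree = 2L, grouping = "sum", n_points = 256L,
                         max_gap = 30) {
  healthy_side <- match.arg(healthy_side)
  log <- character()
  if (inherits(x, "surface_scan")) {
    if (is.null(levels)) {
      zr <- range(x$vertices[, 3L])
      levels <- seq(zr[1L] + 0.15 * diff(zr), zr[1L] + 0.85 * diff(zr),
                    length.out = n_levels)
      log <- c(log, sprintf("auto slice plan: %d levels, z %.1f..%.1f mm",
                            n_levels, min(levels), max(levels)))
    }
    contours <- slice_scan(x, structure(list(levels = levels,
                                             thickness = thickness),
                                        class = "slice_plan"),
                           n_points = n_points, max_gap = max_gap)
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "contour_line"))) {
    contours <- x
  } else stop("'x' must be a surface_scan or a list of contour_line objects")
  if (length(contours) < 2L) stop("fewer than 2 usable slices")

  slices <- list()
  markers <- list()
  for (ct in contours) {
    lv <- ct$level
    res <- tryCatch({
      dip <- detect_dip(ct)
      if (dip$confidence == "none")
        stop("no dip above the depth threshold")
      sym <- fit_reflection_axis(ct, healthy_side = healthy_side,
                                 trim = trim)
      part <- partition_sectors(ct, dip, axis = sym$axis, d = d)
      x_off <- compute_offset(part, grouping = grouping)
      list(level = lv, dip = dip, symmetry = sym, sectors = part,
           x_off = x_off, marker = correct_marker(dip, x_off, lv))
    }, error = function(e) {
      log <<- c(log, sprintf("slice z = %.1f flagged (%s): %s", lv,
                             "contour analysis", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      slices[[length(slices) + 1L]] <- res
      markers[[length(markers) + 1L]] <- res$marker
      if (healthy_side == "auto")
        log <- c(log, sprintf("slice z = %.1f: healthy side chosen: %s",
                              lv, res$symmetry$healthy_side))
    }
  }
  if (length(markers) < 2L)
    stop("fewer than 2 usable markers after slice analysis")

  traj_dip <- assemble_trajectory(markers, source_label = "scanner",
                                  use = "dip")
  traj_cor <- assemble_trajectory(markers, source_label = "corrected",
                                  use = "corrected")
  fit <- fit_polynomial(traj_cor, degree = degree)
  dev <- lateral_deviation(fit)
  structure(list(slices = slices, markers = markers,
                 trajectory_dip = traj_dip,
                 trajectory_corrected = traj_cor, fit = fit,
                 included_angles = included_angles(fit),
                 deviation = dev,
                 params = list(d = d, trim = trim,
                               healthy_side = healthy_side,
                               degree = degree, grouping = grouping,
                               n_points = n_points, thickness = thickness,
                               max_gap = max_gap),
                 log = log),
            class = "scan_analysis")
}

#' @export
print.scan_analysis <- function(x, ...) {
  cat(sprintf("<scan_analysis> %d usable slices\n", length(x$slices)))
  print(x$fit)
  print(x$deviation)
  invisible(x)
}

# serialisable summary of a scan_analysis
.analysis_report <- function(an) {
  list(
    params = an$params,
    slices = lapply(an$slices, function(s) list(
      level_mm = s$level,
      dip = list(x_mm = s$dip$position[1L], y_mm = s$dip$position[2L],
                 depth_mm = s$dip$depth, confidence = s$dip$confidence),
      axis = list(angle_deg = s$symmetry$axis$angle,
                  offset_mm = s$symmetry$axis$offset),
      healthy_side = s$symmetry$healthy_side,
      mismatch_area_mm2 = s$symmetry$mismatch_area,
      sectors = list(A = s$sectors$A, B = s$sectors$B, C = s$sectors$C,
                     D = s$sectors$D, R_omega = s$sectors$R_omega),
      x_off_mm = s$x_off,
      corrected_x_mm = s$marker$corrected_position[1L]
    )),
    fit = list(degree = an$fit$degree,
               coefficients = an$fit$coefficients,
               z_center = an$fit$z_center, z_scale = an$fit$z_scale,
               residual_rms_mm = an$fit$residual_rms,
               inflexion_levels_mm = an$fit$inflexion_levels),
    included_angles_deg = an$included_angles,
    deviation = list(max_lateral_deviation_mm =
                       an$deviation$max_lateral_deviation,
                     severity = an$deviation$severity,
                     baseline = an$deviation$baseline,
                     note = paste("included-angle knots are the curve",
                                  "endpoints plus interior inflexions;",
                                  "axis fit is an automated trimmed",
                                  "least-squares reflection match")),
    log = an$log
  )
}

#' Run the full analysis pipeline from a configuration
#'
#' Deterministic end-to-end run: read the input (PLY surface or contour
#' stack CSV), analyse every slice, fit the trajectory, optionally match
#' it against a reference marker trajectory, and write `report.json` and
#' `trajectory.csv` into the output directory. Every parameter is echoed
#' verbatim into the report; every automated decision (healthy-side
#' choice, skipped slices) is logged.
#'
#' @param config a named list, or path to a YAML/JSON config file, with
#'   elements `input` (PLY or contour-stack CSV path), optional `markers`
#'   (reference marker CSV for curve matching), `out` (output directory,
#'   default `"."`), and any parameter of [analyze_scan()] plus optional
#'   `mask` (list with `xlim`/`ylim`/`zlim`) and `seed`.
#' @return the `scan_analysis`, invisibly, with a `match` element when a
#'   reference was given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the 'yaml' package; use JSON instead")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$input))
  if (!is.null(config$seed)) set.seed(config$seed)
  out_dir <- if (is.null(config$out)) "." else config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  input <- config$input
  x <- if (grepl("\\.ply$", input, ignore.case = TRUE)) {
    scan <- read_surface(input)
    if (!is.null(config$mask))
      scan <- apply_mask(scan, do.call(mask_box, lapply(config$mask,
                                                        as.numeric)))
    scan
  } else read_contours(input)

  keep <- intersect(names(config),
                    names(formals(analyze_scan))[-1L])
  an <- do.call(analyze_scan, c(list(x = x), config[keep]))

  report <- .analysis_report(an)
  report$input <- input
  if (!is.null(config$seed)) report$seed <- config$seed
  if (!is.null(config$markers)) {
    ref <- read_markers(config$markers, source_label = "SP3")
    mt <- match_curves(an$trajectory_corrected, ref)
    an$match <- mt
    report$match <- list(
      reference = config$markers,
      translation_mm = as.numeric(mt$translation),
      rotation_alpha_deg = mt$rotation_alpha,
      optimality_mm2 = mt$optimality,
      definition = "mean squared residual distance after alignment")
  }
  write_report(report, file.path(out_dir, "report.json"))
  tr <- an$trajectory_corrected
  write_markers(marker_set(tr$points[, 3L], tr$points[, 1L],
                           y_mm = tr$points[, 2L],
                           source_label = "corrected"),
                file.path(out_dir, "trajectory.csv"))
  invisible(an)
}
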