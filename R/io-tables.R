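# Marker, contour-stack and trajectory tables (CSV) and the JSON report.
# Markers stand in for the manually placed per-level vertebral positions;
# contour stacks stand in for CT-derived transverse contours.

#' Construct a marker set
#'
#' An ordered set of per-level positions along the vertebral column. Levels
#' (`level_mm`, the z coordinate) must be unique; markers are stored sorted
#' by level. `x_mm` is the lateral position (positive toward the patient's
#' right); `y_mm`, the anterior-posterior position, may be absent for
#' markers digitised from a coronal (X-ray-like) projection.
#'
#' @param level_mm,x_mm,y_mm numeric vectors of equal length (`y_mm` may be
#'   `NULL`).
#' @param source_label one of `"SP1"` (coronal-projection markers), `"SP2"`
#'   (contour-dip markers), `"SP3"` (vertebral-body centres), `"scanner"`,
#'   `"corrected"`, `"other"`.
#' @return a `marker_set`: data frame with columns `level_mm`, `x_mm` and
#'   optionally `y_mm`, plus a `source_label` attribute.
#' @export
marker_set <- function(level_mm, x_mm, y_mm = NULL,
                       source_label = c("other", "SP1", "SP2", "SP3",
                                        "scanner", "corrected")) {
  source_label <- match.arg(source_label)
  level_mm <- as.numeric(level_mm)
  x_mm <- as.numeric(x_mm)
  if (length(level_mm) != length(x_mm))
    stop("level_mm and x_mm lengths differ")
  if (length(level_mm) < 2L)
    stop("a marker set needs at least 2 markers")
  if (!all(is.finite(level_mm)) || !all(is.finite(x_mm)))
    stop("marker coordinates must be finite")
  if (anyDuplicated(level_mm))
    stop("duplicate marker levels: ",
         paste(unique(level_mm[duplicated(level_mm)]), collapse = ", "))
  df <- data.frame(level_mm = level_mm, x_mm = x_mm)
  if (!is.null(y_mm)) {
    y_mm <- as.numeric(y_mm)
    if (length(y_mm) != length(level_mm)) stop("y_mm length differs")
    df$y_mm <- y_mm
  }
  df <- df[order(df$level_mm), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, source_label = source_label,
            class = c("marker_set", "data.frame"))
}

#' Read / write marker sets as CSV
#'
#' The CSV has a header `level_mm,x_mm` with an optional `y_mm` column.
#'
#' @param path CSV path.
#' @param source_label see [marker_set()].
#' @return `read_markers`: a [marker_set()]. `write_markers`: `path`,
#'   invisibly.
#' @export
read_markers <- function(path, source_label = "other") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  if (!all(c("level_mm", "x_mm") %in% names(df)))
    stop("marker CSV must have columns level_mm,x_mm: ", path)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric value in column ", col, ", row ", bad[1L],
           " of ", path, ": ", sQuote(df[[col]][bad[1L]]))
    v
  }
  marker_set(num("level_mm"), num("x_mm"),
             y_mm = if ("y_mm" %in% names(df)) num("y_mm"),
             source_label = source_label)
}

#' @rdname read_markers
#' @param markers a [marker_set()] (or trajectory coerced with
#'   [as_marker_set()]).
#' @export
write_markers <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  utils::write.csv(as.data.frame(markers), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a stack of transverse contour lines as CSV
#'
#' Long-format CSV with columns `level_mm, point_index, x_mm, y_mm`; one row
#' per contour point, points ordered within each level.
#'
#' @param path CSV path.
#' @return `read_contours`: a named list of [contour_line()] objects (names
#'   are the levels in mm, ascending). `write_contours`: `path`, invisibly.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("level_mm", "point_index", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("contour CSV must have columns ", paste(need, collapse = ","))
  if (!all(vapply(df[need], is.numeric, TRUE)))
    stop("non-numeric values in contour CSV ", path)
  levels <- sort(unique(df$level_mm))
  out <- lapply(levels, function(lv) {
    sl <- df[df$level_mm == lv, , drop = FALSE]
    sl <- sl[order(sl$point_index), , drop = FALSE]
    contour_line(cbind(sl$x_mm, sl$y_mm), level = lv)
  })
  names(out) <- levels
  out
}

#' @rdname read_contours
#' @param contours list of [contour_line()] objects.
#' @export
write_contours <- function(contours, path) {
  rows <- lapply(contours, function(ct) {
    stopifnot(inherits(ct, "contour_line"))
    data.frame(level_mm = ct$level,
               point_index = seq_len(nrow(ct$points)) - 1L,
               x_mm = ct$points[, 1L], y_mm = ct$points[, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serialises the nested result list produced by [run_pipeline()] (or
#' assembled by hand) with a schema version stamp. Numbers are written at
#' full precision.
#'
#' @param report a named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  report <- c(list(schema = "spinescan-report/1"), report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
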