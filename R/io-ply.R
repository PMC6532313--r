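# PLY (polygon file format) reader/writer. Body scanners export torso
# meshes in this format; no installed package parses it, so it is done here.
# Supported dialects: ascii 1.0 and binary_little_endian 1.0. Other
# encodings are rejected rather than guessed.

.ply_type_size <- c(
  char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
  float = 4L, float32 = 4L,
  double = 8L, float64 = 8L
)

.ply_read_what <- function(type) {
  if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
}

.ply_is_signed <- function(type) {
  !type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32")
}

.ply_parse_header <- function(lines) {
  if (length(lines) < 3L || trimws(lines[1L]) != "ply")
    stop("not a PLY file: first line is ", sQuote(lines[1L]))
  elements <- list()
  format <- NULL
  unit_scale <- 1
  cur <- NULL
  for (i in seq_along(lines)[-1L]) {
    ln <- trimws(lines[i])
    if (ln == "" || ln == "end_header") break
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    switch(tok[1L],
      format = {
        if (length(tok) < 2L)
          stop("malformed PLY header line ", i, ": ", sQuote(ln))
        format <- tok[2L]
      },
      comment = {
        # honour a unit declaration such as "comment units m"
        if (length(tok) >= 3L && tolower(tok[2L]) %in% c("units", "unit")) {
          unit_scale <- switch(tolower(tok[3L]),
                               mm = 1, cm = 10, m = 1000,
                               stop("unknown unit in PLY header line ", i,
                                    ": ", sQuote(tok[3L])))
        }
      },
      element = {
        if (length(tok) != 3L || is.na(suppressWarnings(as.integer(tok[3L]))))
          stop("malformed PLY header line ", i, ": ", sQuote(ln))
        cur <- length(elements) + 1L
        elements[[cur]] <- list(name = tok[2L],
                                count = as.integer(tok[3L]),
                                props = list())
        names(elements)[cur] <- tok[2L]
      },
      property = {
        if (is.null(cur))
          stop("malformed PLY header line ", i,
               ": property before any element")
        if (tok[2L] == "list") {
          if (length(tok) != 5L)
            stop("malformed PLY header line ", i, ": ", sQuote(ln))
          p <- list(name = tok[5L], list = TRUE,
                    count_type = tok[3L], item_type = tok[4L])
        } else {
          if (length(tok) != 3L || !tok[2L] %in% names(.ply_type_size))
            stop("malformed PLY header line ", i, ": ", sQuote(ln))
          p <- list(name = tok[3L], list = FALSE, type = tok[2L])
        }
        elements[[cur]]$props <- c(elements[[cur]]$props, list(p))
      },
      ply = NULL,
      stop("malformed PLY header line ", i, ": ", sQuote(ln))
    )
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY header: no end_header line")
  if (is.null(format)) stop("malformed PLY header: no format line")
  if (!format %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format ", sQuote(format),
         "; only ascii and binary_little_endian are read")
  list(format = format, elements = elements, unit_scale = unit_scale,
       header_lines = end)
}

.ply_read_binary_element <- function(con, el) {
  props <- el$props
  n <- el$count
  if (n == 0L) return(NULL)
  if (!any(vapply(props, `[[`, TRUE, "list"))) {
    sizes <- vapply(props, function(p) .ply_type_size[[p$type]], 1L)
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = n * stride)
    if (length(raw) < n * stride)
      stop("truncated PLY: element ", el$name, " ends early")
    bytes <- matrix(raw, nrow = stride)
    offs <- cumsum(c(0L, sizes))
    out <- matrix(0, nrow = n, ncol = length(props))
    colnames(out) <- vapply(props, `[[`, "", "name")
    for (j in seq_along(props)) {
      sel <- as.vector(bytes[(offs[j] + 1L):offs[j + 1L], , drop = FALSE])
      out[, j] <- readBin(sel, .ply_read_what(props[[j]]$type), n = n,
                          size = sizes[j], endian = "little",
                          signed = .ply_is_signed(props[[j]]$type))
    }
    return(out)
  }
  # list properties (faces): fast path when every list has 3 items
  if (length(props) != 1L || !props[[1L]]$list)
    stop("unsupported PLY: element ", el$name,
         " mixes list and scalar properties")
  p <- props[[1L]]
  csz <- .ply_type_size[[p$count_type]]
  isz <- .ply_type_size[[p$item_type]]
  first_cnt <- readBin(con, .ply_read_what(p$count_type), n = 1L, size = csz,
                       endian = "little", signed = .ply_is_signed(p$count_type))
  if (length(first_cnt) == 0L)
    stop("truncated PLY: element ", el$name, " ends early")
  k <- first_cnt
  stride <- csz + k * isz
  raw <- readBin(con, "raw", n = n * stride - csz)
  raw <- c(writeBin(as.integer(first_cnt), raw(), size = csz,
                    endian = "little"), raw)
  if (length(raw) < n * stride)
    stop("truncated PLY: element ", el$name, " ends early")
  bytes <- matrix(raw[seq_len(n * stride)], nrow = stride)
  cnts <- readBin(as.vector(bytes[seq_len(csz), , drop = FALSE]),
                  .ply_read_what(p$count_type), n = n, size = csz,
                  endian = "little", signed = .ply_is_signed(p$count_type))
  if (!all(cnts == k))
    stop("unsupported PLY: face lists of varying length in binary file")
  out <- matrix(0L, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    o <- csz + (j - 1L) * isz
    sel <- as.vector(bytes[(o + 1L):(o + isz), , drop = FALSE])
    out[, j] <- readBin(sel, .ply_read_what(p$item_type), n = n, size = isz,
                        endian = "little", signed = .ply_is_signed(p$item_type))
  }
  out
}

#' Read a torso surface mesh from a PLY file
#'
#' Reads ASCII or binary little-endian PLY. Vertex `x`, `y`, `z` properties
#' are required; additional vertex properties (normals, colour) are parsed
#' and discarded — the analysis never uses them. Triangle faces are kept
#' when present. Coordinates are converted to mm when the header carries a
#' `comment units {mm|cm|m}` declaration.
#'
#' @param path path to a `.ply` file.
#' @return a [surface_scan()] in mm.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII; read it line-wise from the binary connection
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("malformed PLY header: no end_header line")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 500L) stop("malformed PLY header: runaway header")
  }
  hd <- .ply_parse_header(header)
  vel <- hd$elements[["vertex"]]
  if (is.null(vel)) stop("PLY file has no vertex element")
  if (vel$count == 0L) stop("PLY file declares zero vertices")
  fel <- hd$elements[["face"]]

  if (hd$format == "ascii") {
    tok <- scan(con, what = double(), quiet = TRUE,
                comment.char = "")
    data <- list()
    pos <- 0L
    for (el in hd$elements) {
      if (el$count == 0L) { data[[el$name]] <- NULL; next }
      if (!any(vapply(el$props, `[[`, TRUE, "list"))) {
        p <- length(el$props)
        need <- el$count * p
        if (pos + need > length(tok))
          stop("truncated PLY: element ", el$name, " ends early")
        m <- matrix(tok[pos + seq_len(need)], ncol = p, byrow = TRUE)
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        data[[el$name]] <- m
        pos <- pos + need
      } else {
        rows <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          k <- tok[pos + 1L]
          if (is.na(k) || pos + 1L + k > length(tok))
            stop("truncated PLY: element ", el$name, " ends early")
          rows[[i]] <- tok[pos + 1L + seq_len(k)]
          pos <- pos + 1L + k
        }
        lens <- lengths(rows)
        if (!all(lens == lens[1L]))
          stop("unsupported PLY: face lists of varying length")
        data[[el$name]] <- matrix(unlist(rows), ncol = lens[1L], byrow = TRUE)
      }
    }
  } else {
    data <- list()
    for (el in hd$elements)
      data[[el$name]] <- .ply_read_binary_element(con, el)
  }

  vm <- data[["vertex"]]
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(vm)))
    stop("PLY vertex element lacks x, y, z properties")
  vertices <- vm[, need, drop = FALSE] * hd$unit_scale
  faces <- NULL
  if (!is.null(fel) && !is.null(data[["face"]])) {
    fm <- data[["face"]]
    if (ncol(fm) != 3L)
      stop("only triangle faces are supported, found ", ncol(fm), "-gons")
    faces <- fm + 1L  # PLY indices are 0-based
  }
  surface_scan(vertices, faces, provenance = path)
}

#' Write a surface scan to a PLY file
#'
#' @param scan a [surface_scan()].
#' @param path output path.
#' @param format `"ascii"` (default, 1e-6 mm precision) or `"binary"`
#'   (binary little-endian, float64 coordinates).
#' @return `path`, invisibly.
#' @export
write_surface <- function(scan, path, format = c("ascii", "binary")) {
  stopifnot(inherits(scan, "surface_scan"))
  format <- match.arg(format)
  v <- scan$vertices
  f <- scan$faces
  vtype <- if (format == "ascii") "float" else "double"
  header <- c(
    "ply",
    paste("format",
          if (format == "ascii") "ascii" else "binary_little_endian", "1.0"),
    "comment units mm",
    paste("element vertex", nrow(v)),
    paste("property", vtype, "x"),
    paste("property", vtype, "y"),
    paste("property", vtype, "z"),
    if (!is.null(f)) c(paste("element face", nrow(f)),
                       "property list uchar int vertex_indices"),
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (format == "ascii") {
    writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    if (!is.null(f))
      writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
                 con)
  } else {
    writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
    if (!is.null(f)) {
      idx <- writeBin(as.integer(t(f) - 1L), raw(), size = 4L,
                      endian = "little")
      rec <- matrix(raw(), nrow = 13L, ncol = nrow(f))
      rec[1L, ] <- as.raw(3L)
      rec[-1L, ] <- matrix(idx, nrow = 12L)
      writeBin(as.vector(rec), con)
    }
  }
  invisible(path)
}
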