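#' Read a triangulated surface from STL, PLY or OFF
#'
#' STL files (ASCII or binary, auto-detected) store a triangle soup; on read,
#' bitwise-identical vertices are merged keeping first-occurrence order, which
#' restores shared connectivity for files written by [write_surface()].
#' PLY (ASCII) and OFF preserve indexed connectivity exactly.
#'
#' @param path file path.
#' @param format one of "stl", "ply", "off"; guessed from the extension when
#'   missing.
#' @param label label for the returned surface.
#' @return a [tri_surface].
#' @export
read_surface <- function(path, format = NULL, label = NULL) {
  if (!file.exists(path)) stop("cannot read surface: file not found: ", path)
  format <- resolve_surface_format(path, format)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
    stl = read_stl(path, label),
    ply = read_ply(path, label),
    off = read_off(path, label),
    stop("unsupported surface format: ", format)
  )
}

#' Write a triangulated surface to STL, PLY or OFF
#'
#' @param surface a [tri_surface].
#' @param path output path.
#' @param format one of "stl", "ply", "off"; guessed from the extension.
#' @param binary for STL only: write the 50-byte-record binary layout instead
#'   of ASCII.
#' @param scalars optional named list of per-vertex numeric vectors, written
#'   as extra vertex properties (PLY only).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, format = NULL, binary = FALSE,
                          scalars = NULL) {
  stopifnot(inherits(surface, "tri_surface"))
  format <- resolve_surface_format(path, format)
  switch(format,
    stl = write_stl(surface, path, binary),
    ply = write_ply(surface, path, scalars),
    off = write_off(surface, path),
    stop("unsupported surface format: ", format)
  )
  invisible(path)
}

resolve_surface_format <- function(path, format) {
  if (is.null(format)) format <- tolower(sub(".*\\.", "", path))
  format <- tolower(format)
  if (!format %in% c("stl", "ply", "off")) {
    stop("surface format must be one of stl, ply, off (got '", format, "')")
  }
  format
}

# ---- STL ----

stl_is_binary <- function(path) {
  n <- file.size(path)
  if (n < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  if (identical(expected, as.numeric(n))) return(TRUE)
  !grepl("^\\s*solid", rawToChar(header[header != as.raw(0)]))
}

read_stl <- function(path, label) {
  tri <- if (stl_is_binary(path)) read_stl_binary(path) else read_stl_ascii(path)
  if (nrow(tri) == 0L || nrow(tri) %% 3L != 0L) {
    stop("malformed STL file (truncated or empty): ", path)
  }
  key <- apply(tri, 1, paste, collapse = " ")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  verts <- tri[first, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_surface(verts, faces, label = label)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) return(matrix(numeric(0), ncol = 3))
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  m <- do.call(rbind, nums)
  if (any(!is.finite(m))) stop("malformed vertex line in ASCII STL: ", path)
  m
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ntri <= 0) stop("malformed binary STL: ", path)
  rec <- readBin(con, "raw", 50 * ntri)
  if (length(rec) < 50 * ntri) stop("truncated binary STL: ", path)
  dim(rec) <- c(50, ntri)
  vb <- rec[13:48, , drop = FALSE]  # 9 floats after the normal
  vals <- readBin(as.raw(vb), "numeric", size = 4, n = 9 * ntri,
                  endian = "little")
  matrix(vals, ncol = 3, byrow = TRUE)
}

write_stl <- function(surface, path, binary) {
  v <- surface$vertices
  f <- surface$faces
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("bramax", surface$label)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- tri_normal(tri)
      writeBin(as.numeric(c(n, t(tri))), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", surface$label), con)
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      n <- tri_normal(tri)
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
        "    endloop",
        "  endfacet"
      ), con)
    }
    writeLines(sprintf("endsolid %s", surface$label), con)
  }
}

tri_normal <- function(tri) {
  n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
  len <- sqrt(sum(n^2))
  if (len > 0) n / len else c(0, 0, 0)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- PLY (ASCII) ----

read_ply <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "ply") stop("not a PLY file: ", path)
  end_hdr <- match("end_header", lines)
  if (is.na(end_hdr)) stop("malformed PLY header (no end_header): ", path)
  hdr <- lines[seq_len(end_hdr)]
  if (!any(grepl("^format ascii", hdr))) {
    stop("only ASCII PLY is supported: ", path)
  }
  elem_lines <- grep("^element ", hdr)
  nvert <- nface <- 0L
  vert_props <- character(0)
  cur <- ""
  for (i in seq_along(hdr)) {
    tok <- strsplit(trimws(hdr[i]), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      if (cur == "vertex") nvert <- as.integer(tok[3])
      if (cur == "face") nface <- as.integer(tok[3])
    } else if (tok[1] == "property" && cur == "vertex" && tok[2] != "list") {
      vert_props <- c(vert_props, tok[3])
    }
  }
  body <- lines[(end_hdr + 1):length(lines)]
  if (length(body) < nvert + nface) stop("truncated PLY body: ", path)
  vdat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nvert)]), "\\s+"),
                                as.numeric))
  colnames(vdat) <- vert_props
  fdat <- strsplit(trimws(body[nvert + seq_len(nface)]), "\\s+")
  counts <- vapply(fdat, function(x) as.integer(x[1]), integer(1))
  if (any(counts != 3L)) stop("non-triangular face in PLY file: ", path)
  faces <- do.call(rbind, lapply(fdat, function(x) as.integer(x[2:4]))) + 1L
  s <- tri_surface(vdat[, c("x", "y", "z"), drop = FALSE], faces, label)
  extra <- setdiff(vert_props, c("x", "y", "z"))
  if (length(extra)) {
    s$scalars <- lapply(setNames(extra, extra), function(p) vdat[, p])
  }
  s
}

write_ply <- function(surface, path, scalars = NULL) {
  v <- surface$vertices
  f <- surface$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment bramax %s", surface$label),
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z")
  cols <- list(v[, 1], v[, 2], v[, 3])
  for (nm in names(scalars)) {
    stopifnot(length(scalars[[nm]]) == nrow(v))
    hdr <- c(hdr, sprintf("property double %s", nm))
    cols <- c(cols, list(as.numeric(scalars[[nm]])))
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- do.call(cbind, cols)
  writeLines(apply(vm, 1, function(r) paste(sprintf("%.17g", r),
                                            collapse = " ")), con)
  writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
}

# ---- OFF ----

read_off <- function(path, label) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines) || trimws(lines[1]) != "OFF") {
    stop("not an OFF file: ", path)
  }
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) stop("truncated OFF file: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(lines[2 + seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  frows <- strsplit(trimws(lines[2 + nv + seq_len(nf)]), "\\s+")
  counts <- vapply(frows, function(x) as.integer(x[1]), integer(1))
  if (any(counts != 3L)) stop("non-triangular face in OFF file: ", path)
  f <- do.call(rbind, lapply(frows, function(x) as.integer(x[2:4]))) + 1L
  tri_surface(v, f, label)
}

write_off <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- surface$vertices
  f <- surface$faces - 1L
  writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f))), con)
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), con)
  writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
}
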