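#' Triangulated surface
#'
#' Container for a triangulated surface mesh in the patient frame
#' (+x patient-left, +y anterior, +z superior; all coordinates in mm).
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param label free-text tag, e.g. "face", "airway", "maxilla".
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, label = "surface") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix of vertex indices")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  structure(
    list(vertices = vertices, faces = faces, label = as.character(label)[1]),
    class = "tri_surface"
  )
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("tri_surface '%s': %d vertices, %d faces\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Per-face areas of a triangulated surface
#'
#' @param surface a [tri_surface].
#' @return numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Undirected edge table with multiplicity; edges keyed as "lo-hi".
surface_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  paste(lo, hi, sep = "-")
}

#' Watertightness test
#'
#' A closed orientable triangle mesh has every undirected edge shared by
#' exactly two faces.
#'
#' @param surface a [tri_surface].
#' @return logical scalar.
#' @export
is_watertight <- function(surface) {
  if (nrow(surface$faces) == 0L) return(FALSE)
  tab <- table(surface_edges(surface))
  all(tab == 2L)
}

#' Mesh validation report
#'
#' Report-only checks shared by surfaces and tetrahedral meshes: degenerate
#' (zero-area) triangles, negative/zero tetrahedron volumes, duplicate
#' vertices (within 1e-6 mm), non-manifold edges, and watertightness for
#' surfaces. `ok` is TRUE iff no blocking defect was found.
#'
#' @param x a [tri_surface] or [tet_mesh].
#' @param duplicate_tol duplicate-vertex tolerance in mm.
#' @return An object of class `validation_report`.
#' @export
validate_mesh <- function(x, duplicate_tol = 1e-6) {
  UseMethod("validate_mesh")
}

find_duplicate_vertices <- function(pts, tol) {
  key <- apply(round(pts / tol), 1, paste, collapse = ",")
  sum(duplicated(key))
}

#' @export
validate_mesh.tri_surface <- function(x, duplicate_tol = 1e-6) {
  areas <- face_areas(x)
  tab <- table(surface_edges(x))
  report <- list(
    kind = "tri_surface",
    n_degenerate_faces = sum(areas <= .Machine$double.eps * 100),
    n_duplicate_vertices = find_duplicate_vertices(x$vertices, duplicate_tol),
    n_nonmanifold_edges = sum(tab > 2L),
    watertight = nrow(x$faces) > 0L && all(tab == 2L),
    n_negative_volumes = 0L
  )
  report$ok <- report$n_degenerate_faces == 0L &&
    report$n_nonmanifold_edges == 0L
  structure(report, class = "validation_report")
}

#' @export
validate_mesh.tet_mesh <- function(x, duplicate_tol = 1e-6) {
  vols <- tet_volumes(x)
  bad_sets <- vapply(x$node_sets, function(s) {
    length(s) > 0L && (min(s) < 1L || max(s) > nrow(x$nodes))
  }, logical(1))
  report <- list(
    kind = "tet_mesh",
    n_negative_volumes = sum(vols <= 0),
    n_duplicate_vertices = find_duplicate_vertices(x$nodes, duplicate_tol),
    n_invalid_node_sets = sum(bad_sets),
    n_nonmanifold_edges = 0L,
    watertight = NA
  )
  report$ok <- report$n_negative_volumes == 0L &&
    report$n_invalid_node_sets == 0L
  structure(report, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report (%s): %s\n", x$kind,
              if (isTRUE(x$ok)) "ok" else "DEFECTS FOUND"))
  for (nm in setdiff(names(x), c("kind", "ok"))) {
    cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
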