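#' Tetrahedral volume mesh
#'
#' Container for an unstructured 4-node tetrahedral mesh with per-element
#' material-region tags and named node sets. The node-ordering convention is
#' right-handed: the signed volume det([b-a, c-a, d-a]) / 6 of every element
#' must be positive.
#'
#' @param nodes numeric n x 3 matrix of node coordinates (mm).
#' @param tets integer m x 4 matrix of 1-based node indices.
#' @param region character vector (length m) of material tags per element,
#'   e.g. "soft_tissue" or "bone"; air regions are represented as voids and
#'   carry no elements.
#' @param node_sets named list of integer node-index vectors (e.g.
#'   `maxilla_surface`, `mandible_surface`, `fixed_skull`, `face_skin`,
#'   `airway_wall`).
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, region = NULL, node_sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(tets) != 4L) stop("tets must be an m x 4 matrix of node indices")
  if (nrow(tets) > 0L && (min(tets) < 1L || max(tets) > nrow(nodes))) {
    stop("tet node indices out of range")
  }
  if (is.null(region)) region <- rep("soft_tissue", nrow(tets))
  region <- as.character(region)
  if (length(region) != nrow(tets)) {
    stop("region must supply exactly one tag per tet")
  }
  if (!is.list(node_sets)) stop("node_sets must be a named list")
  node_sets <- lapply(node_sets, function(s) sort(unique(as.integer(s))))
  structure(
    list(nodes = nodes, tets = tets, region = region, node_sets = node_sets),
    class = "tet_mesh"
  )
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets\n", nrow(x$nodes), nrow(x$tets)))
  cat("  regions:", paste(sprintf("%s (%d)", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  if (length(x$node_sets)) {
    cat("  node sets:", paste(sprintf("%s (%d)", names(x$node_sets),
                                      lengths(x$node_sets)),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param mesh a [tet_mesh].
#' @return numeric vector of signed volumes (mm^3), positive under the
#'   package's node-ordering convention.
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes
  t <- mesh$tets
  a <- n[t[, 1], , drop = FALSE]
  b <- n[t[, 2], , drop = FALSE] - a
  c_ <- n[t[, 3], , drop = FALSE] - a
  d <- n[t[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Boundary surface of a tetrahedral mesh
#'
#' Extracts the faces that belong to exactly one tetrahedron, oriented
#' outward, optionally restricted to a subset of elements.
#'
#' @param mesh a [tet_mesh].
#' @param elements optional integer vector of element indices to restrict to.
#' @param label label for the resulting surface.
#' @return a [tri_surface] whose vertices are the mesh nodes (all of them;
#'   face indices refer to mesh node numbering).
#' @export
boundary_surface <- function(mesh, elements = NULL, label = "boundary") {
  t <- mesh$tets
  if (!is.null(elements)) t <- t[elements, , drop = FALSE]
  # Outward-oriented faces of a positively oriented tet (1,2,3,4):
  faces <- rbind(t[, c(1, 3, 2), drop = FALSE],
                 t[, c(1, 2, 4), drop = FALSE],
                 t[, c(2, 3, 4), drop = FALSE],
                 t[, c(1, 4, 3), drop = FALSE])
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  keep <- !(key %in% key[duplicated(key)])
  tri_surface(mesh$nodes, faces[keep, , drop = FALSE], label = label)
}
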