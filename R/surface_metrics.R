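#' Shortest distance from points to a triangulated surface
#'
#' Exact minimum Euclidean point-to-triangle distance over all triangles of
#' the surface, with the foot point. A uniform-grid spatial index
#' accelerates the query; its results are defined to equal the brute-force
#' loop over all triangles (the brute-force path is kept available as the
#' correctness oracle).
#'
#' @param points n x 3 matrix (or a single 3-vector) of query points (mm).
#' @param surface a non-empty [tri_surface].
#' @param accelerate use the spatial index (default) or the brute-force
#'   reference loop.
#' @return list with `distance` (mm), `foot` (n x 3 closest points) and
#'   `triangle` (index of the supporting triangle).
#' @export
point_to_surface_distance <- function(points, surface, accelerate = TRUE) {
  stopifnot(inherits(surface, "tri_surface"))
  if (nrow(surface$faces) == 0L) stop("surface has no triangles")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  .point_surface_distance(as.matrix(points), surface$vertices,
                          surface$faces, isTRUE(accelerate))
}

#' Bijective surface-distance map
#'
#' For each node `a` of surface A the map records the maximum shortest
#' bijective distance `d_min(a) = max(fwd(a), bwd(a))`: `fwd(a)` is the
#' shortest distance from `a` to surface B, and `bwd(a)` is the largest of
#' the shortest distances from B-nodes back to A among those B-nodes whose
#' foot point on A is nearest to `a` (none assigned: `bwd = fwd`). Taking
#' the maximum of the two directions avoids the artificially short values a
#' unidirectional distance produces between two convex surfaces. The two
#' surfaces must already be rigidly registered.
#'
#' @param A,B [tri_surface] objects, registered to a common frame.
#' @param accelerate use the spatial index for the distance queries.
#' @return An object of class `distance_map`: per-A-node `dmin`, `forward`,
#'   `backward` (mm), the assignment counts, and an all-true relevance mask
#'   (see [relevance_mask()]).
#' @export
dmin_map <- function(A, B, accelerate = TRUE) {
  stopifnot(inherits(A, "tri_surface"), inherits(B, "tri_surface"))
  if (!nrow(A$vertices) || !nrow(B$vertices)) stop("empty surface")
  fwd <- point_to_surface_distance(A$vertices, B, accelerate)$distance
  back_q <- point_to_surface_distance(B$vertices, A, accelerate)
  # assign each B-node's backward distance to the A-node nearest its foot
  # point on A; ties resolved to the lowest node index by the kernel
  owner <- .nearest_vertex(back_q$foot, A$vertices)
  bwd <- fwd
  agg <- tapply(back_q$distance, owner, max)
  idx <- as.integer(names(agg))
  bwd[idx] <- pmax(bwd[idx], as.numeric(agg))
  structure(list(
    dmin = pmax(fwd, bwd),
    forward = fwd,
    backward = bwd,
    mask = rep(TRUE, length(fwd)),
    n_assigned = length(idx)
  ), class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  s <- summarize_distance_map(x)
  cat(sprintf(
    "distance_map: %d nodes (%d masked), mean d_min %.4f mm, sd %.4f mm\n",
    length(x$dmin), s$n_masked, s$mean, s$sd))
  invisible(x)
}

#' Relevant-region mask from predicted displacements
#'
#' The evaluation of facial predictions is restricted to the surface region
#' where the simulated displacement magnitude exceeds a threshold (0.1 mm by
#' default), excluding regions dominated by geometric noise.
#'
#' @param displacement n x 3 matrix of predicted displacements on the
#'   surface nodes (mm).
#' @param threshold magnitude threshold (mm).
#' @return logical vector, TRUE where `|u| > threshold`.
#' @export
relevance_mask <- function(displacement, threshold = 0.1) {
  displacement <- as.matrix(displacement)
  sqrt(rowSums(displacement^2)) > threshold
}

#' Apply a relevance mask to a distance map
#'
#' @param map a `distance_map`.
#' @param mask logical vector, one entry per A-node.
#' @return the map with the mask replaced.
#' @export
mask_distance_map <- function(map, mask) {
  stopifnot(inherits(map, "distance_map"),
            length(mask) == length(map$dmin))
  map$mask <- as.logical(mask)
  map
}

#' Mean / sd summary of a masked distance map
#'
#' @param map a `distance_map`.
#' @return list with `mean`, `sd` (sample, n-1) in mm and `n_masked`.
#' @export
summarize_distance_map <- function(map) {
  stopifnot(inherits(map, "distance_map"))
  v <- map$dmin[map$mask]
  if (!length(v)) {
    stop("empty relevance mask: no nodes to summarize (distinct from zero distance)")
  }
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n_masked = length(v))
}

#' Write a distance map as PLY with a per-vertex scalar
#'
#' @param map a `distance_map`.
#' @param surface the A surface the map lives on.
#' @param path output PLY path.
#' @export
write_distance_map <- function(map, surface, path) {
  write_surface(surface, path, format = "ply",
                scalars = list(dmin = map$dmin,
                               masked = as.numeric(map$mask)))
  invisible(path)
}
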