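#' Rigid transform with explicit rotation center
#'
#' Applies `p -> R (p - center) + center + translation`. Used both for
#' landmark-based alignment of pre-/post-surgery and simulated models and for
#' the planned jaw displacements (rotation about a shifted center).
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation numeric 3-vector (mm).
#' @param center numeric 3-vector (mm), the point the rotation pivots about.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)),
            length(translation) == 3, length(center) == 3)
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be proper orthogonal (det +1, R'R = I)")
  }
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  center (%.3f, %.3f, %.3f) mm\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Least-squares rigid transform from matched landmarks
#'
#' Closed-form Kabsch/SVD solution for the proper rigid motion (no scaling,
#' no reflection) minimizing the sum of squared distances between matched
#' point pairs. Landmarks are matched by name when both arguments are
#' [landmarks] objects; plain matrices are matched by row order.
#'
#' @param source,target matched points: [landmarks] objects or n x 3 matrices.
#' @return a [rigid_transform] with `center` at the source centroid.
#' @export
rigid_from_landmarks <- function(source, target) {
  if (inherits(source, "landmarks")) source <- landmark_matrix(source)
  if (inherits(target, "landmarks")) target <- landmark_matrix(target)
  if (!is.null(rownames(source)) && !is.null(rownames(target))) {
    common <- intersect(rownames(source), rownames(target))
    source <- source[common, , drop = FALSE]
    target <- target[common, , drop = FALSE]
  }
  n <- nrow(source)
  if (n < 3 || nrow(target) != n) {
    stop("need at least 3 matched landmark pairs")
  }
  cs <- colMeans(source)
  ct <- colMeans(target)
  S <- sweep(source, 2, cs)
  T_ <- sweep(target, 2, ct)
  # Degeneracy: collinear configurations leave a rotation DOF unresolved.
  sv_cfg <- svd(S)$d
  if (sv_cfg[2] < 1e-9 * max(sv_cfg[1], 1)) {
    stop("degenerate landmark configuration (collinear points)")
  }
  H <- crossprod(S, T_)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  rigid_transform(rotation = R, translation = ct - cs, center = cs)
}

#' Apply a rigid transform to points or a surface
#'
#' @param transform a [rigid_transform].
#' @param x an n x 3 matrix, a numeric 3-vector, a [tri_surface] or a
#'   [landmarks] object.
#' @return the transformed object, same type and connectivity as `x`.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "tri_surface")) {
    x$vertices <- apply_transform(transform, x$vertices)
    return(x)
  }
  if (inherits(x, "landmarks")) {
    m <- apply_transform(transform, landmark_matrix(x))
    x[, c("x", "y", "z")] <- m
    return(x)
  }
  vec <- is.null(dim(x))
  p <- if (vec) matrix(x, 1, 3) else as.matrix(x)
  q <- sweep(p, 2, transform$center)
  q <- q %*% t(transform$rotation)
  q <- sweep(q, 2, transform$center + transform$translation, "+")
  if (vec) as.numeric(q) else q
}

#' Compose two rigid transforms (first `b`, then `a`)
#'
#' @param a,b [rigid_transform] objects.
#' @return a [rigid_transform] equal to `x -> a(b(x))`, expressed with
#'   center at the origin.
#' @export
compose_transform <- function(a, b) {
  # a(b(p)) = Ra Rb p + Ra tb0 + ta0 with each transform in
  # origin-centered form p -> R p + t0, t0 = -R c + c + t.
  t0 <- function(T_) -T_$rotation %*% T_$center + T_$center + T_$translation
  R <- a$rotation %*% b$rotation
  t_ <- a$rotation %*% t0(b) + t0(a)
  rigid_transform(rotation = R, translation = as.numeric(t_),
                  center = c(0, 0, 0))
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform].
#' @return the inverse [rigid_transform].
#' @export
invert_transform <- function(transform) {
  t0 <- -transform$rotation %*% transform$center + transform$center +
    transform$translation
  Rinv <- t(transform$rotation)
  rigid_transform(rotation = Rinv, translation = as.numeric(-Rinv %*% t0),
                  center = c(0, 0, 0))
}

#' Root-mean-square landmark residual of a rigid alignment
#'
#' @param transform a [rigid_transform].
#' @param source,target matched points ([landmarks] or n x 3 matrices,
#'   matched by name when named).
#' @return RMS pair distance (mm) after applying `transform` to `source`.
#' @export
registration_residual <- function(transform, source, target) {
  if (inherits(source, "landmarks")) source <- landmark_matrix(source)
  if (inherits(target, "landmarks")) target <- landmark_matrix(target)
  if (!is.null(rownames(source)) && !is.null(rownames(target))) {
    common <- intersect(rownames(source), rownames(target))
    source <- source[common, , drop = FALSE]
    target <- target[common, , drop = FALSE]
  }
  moved <- apply_transform(transform, source)
  sqrt(mean(rowSums((moved - target)^2)))
}

#' Serialize / restore a rigid transform as JSON
#'
#' @param transform a [rigid_transform].
#' @param path file path.
#' @return `read_transform_json` returns a [rigid_transform].
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = as.numeric(t(transform$rotation)),  # row-major
         translation = transform$translation,
         center = transform$center),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(rotation = matrix(lst$rotation, 3, 3, byrow = TRUE),
                  translation = lst$translation, center = lst$center)
}
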