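#' Analytic reference shapes for oracle tests
#'
#' Generates surfaces and tet meshes with closed-form areas/volumes:
#' \describe{
#'   \item{cylinder}{closed tube of radius `radius`, length `length` along
#'     +z starting at z = 0; every z-slice has area pi r^2.}
#'   \item{hourglass}{tube whose radius narrows smoothly to `waist_radius`
#'     at `waist_z` over axial extent `waist_extent` (cosine-squared
#'     profile), the analytic stand-in for a velopharyngeal constriction.}
#'   \item{sphere}{UV sphere of radius `radius` centered at the origin.}
#'   \item{cube}{axis-aligned box `size` (12 triangles), corner at origin.}
#'   \item{parallel_plates}{two parallel square triangulated plates with
#'     separation `gap`; returns `list(A, B)` for distance-metric oracles.}
#'   \item{unit_tet_block}{tetrahedral mesh of an axis-aligned box
#'     (conforming 6-tet subdivision per lattice cell), optionally with
#'     interior nodes jittered to make it unstructured.}
#' }
#'
#' @param kind one of "cylinder", "hourglass", "sphere", "cube",
#'   "parallel_plates", "unit_tet_block".
#' @param ... shape parameters, see Details.
#' @return a [tri_surface], a [tet_mesh] or (parallel_plates) a list of two
#'   surfaces.
#' @export
make_fixture <- function(kind, ...) {
  switch(kind,
    cylinder = fixture_tube(..., profile = NULL),
    hourglass = fixture_hourglass(...),
    sphere = fixture_sphere(...),
    cube = fixture_cube(...),
    parallel_plates = fixture_plates(...),
    unit_tet_block = fixture_tet_block(...),
    stop("unknown fixture kind: ", kind)
  )
}

# Closed surface of revolution around the z axis with radius profile r(z).
fixture_tube <- function(radius = 10, length = 50, n_theta = 96,
                         dz = 1, center_xy = c(0, 0), z0 = 0,
                         profile = NULL, label = "cylinder") {
  if (is.null(profile)) profile <- function(z) rep(radius, length(z))
  zs <- seq(z0, z0 + length, by = dz)
  if (zs[length(zs)] < z0 + length) zs <- c(zs, z0 + length)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  r <- profile(zs)
  nv <- length(zs) * n_theta
  verts <- matrix(0, nv + 2, 3)
  for (i in seq_along(zs)) {
    idx <- (i - 1) * n_theta + seq_len(n_theta)
    verts[idx, 1] <- center_xy[1] + r[i] * cos(theta)
    verts[idx, 2] <- center_xy[2] + r[i] * sin(theta)
    verts[idx, 3] <- zs[i]
  }
  bot_c <- nv + 1
  top_c <- nv + 2
  verts[bot_c, ] <- c(center_xy, z0)
  verts[top_c, ] <- c(center_xy, z0 + length)
  faces <- list()
  for (i in seq_len(length(zs) - 1)) {
    a <- (i - 1) * n_theta + seq_len(n_theta)
    b <- a %% (n_theta) + (i - 1) * n_theta + 1 # next around the ring
    a2 <- a + n_theta
    b2 <- b + n_theta
    faces[[length(faces) + 1]] <- cbind(a, b, b2)
    faces[[length(faces) + 1]] <- cbind(a, b2, a2)
  }
  ring1 <- seq_len(n_theta)
  ringN <- (length(zs) - 1) * n_theta + seq_len(n_theta)
  nxt <- function(v) c(v[-1], v[1])
  faces[[length(faces) + 1]] <- cbind(nxt(ring1), ring1, bot_c)
  faces[[length(faces) + 1]] <- cbind(ringN, nxt(ringN), top_c)
  tri_surface(verts, do.call(rbind, faces), label = label)
}

fixture_hourglass <- function(radius = 10, waist_radius = 5, length = 50,
                              waist_z = NULL, waist_extent = 10,
                              n_theta = 96, dz = 0.5, z0 = 0,
                              center_xy = c(0, 0)) {
  if (is.null(waist_z)) waist_z <- z0 + length / 2
  prof <- function(z) {
    r <- rep(radius, length(z))
    inside <- abs(z - waist_z) <= waist_extent
    r[inside] <- radius - (radius - waist_radius) *
      cos(pi * (z[inside] - waist_z) / (2 * waist_extent))^2
    r
  }
  s <- fixture_tube(radius = radius, length = length, n_theta = n_theta,
                    dz = dz, center_xy = center_xy, z0 = z0,
                    profile = prof, label = "hourglass")
  # make sure a ring sits exactly at the waist
  s
}

fixture_sphere <- function(radius = 1, n_theta = 64, n_phi = 32) {
  phi <- seq(0, pi, length.out = n_phi + 1)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  rings <- phi[-c(1, n_phi + 1)]
  nv <- length(rings) * n_theta
  verts <- matrix(0, nv + 2, 3)
  for (i in seq_along(rings)) {
    idx <- (i - 1) * n_theta + seq_len(n_theta)
    verts[idx, ] <- cbind(radius * sin(rings[i]) * cos(theta),
                          radius * sin(rings[i]) * sin(theta),
                          radius * cos(rings[i]))
  }
  north <- nv + 1
  south <- nv + 2
  verts[north, ] <- c(0, 0, radius)
  verts[south, ] <- c(0, 0, -radius)
  faces <- list()
  nxt <- function(v) c(v[-1], v[1])
  r1 <- seq_len(n_theta)
  faces[[1]] <- cbind(r1, nxt(r1), north)
  for (i in seq_len(length(rings) - 1)) {
    a <- (i - 1) * n_theta + seq_len(n_theta)
    a2 <- a + n_theta
    faces[[length(faces) + 1]] <- cbind(nxt(a), a, a2)
    faces[[length(faces) + 1]] <- cbind(nxt(a), a2, nxt(a2))
  }
  rN <- (length(rings) - 1) * n_theta + seq_len(n_theta)
  faces[[length(faces) + 1]] <- cbind(nxt(rN), rN, south)
  tri_surface(verts, do.call(rbind, faces), label = "sphere")
}

fixture_cube <- function(size = c(1, 1, 1), origin = c(0, 0, 0)) {
  size <- rep(size, length.out = 3)
  corners <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  verts <- sweep(sweep(corners, 2, size, "*"), 2, origin, "+")
  # outward-oriented triangles of the unit cube (corner order of expand.grid)
  faces <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  tri_surface(verts, faces, label = "cube")
}

fixture_plates <- function(gap = 1, size = 20, n = 10) {
  grid_plate <- function(z, label) {
    xs <- seq(-size / 2, size / 2, length.out = n + 1)
    g <- as.matrix(expand.grid(x = xs, y = xs))
    verts <- cbind(g, z)
    id <- function(i, j) (j - 1) * (n + 1) + i
    faces <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        faces[[length(faces) + 1]] <-
          rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
      }
    }
    tri_surface(verts, do.call(rbind, faces), label = label)
  }
  list(A = grid_plate(0, "plate_A"), B = grid_plate(gap, "plate_B"))
}

# Conforming 6-tet (Kuhn) subdivision of each lattice cell of a box.
fixture_tet_block <- function(size = c(1, 1, 1), n = c(4, 4, 4),
                              origin = c(0, 0, 0), jitter = 0, seed = 1L) {
  size <- rep(size, length.out = 3)
  n <- rep(as.integer(n), length.out = 3)
  xs <- seq(0, size[1], length.out = n[1] + 1)
  ys <- seq(0, size[2], length.out = n[2] + 1)
  zs <- seq(0, size[3], length.out = n[3] + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nodes <- sweep(nodes, 2, origin, "+")
  if (jitter > 0) {
    set.seed(as.integer(seed))
    interior <- nodes[, 1] > origin[1] + 1e-12 &
      nodes[, 1] < origin[1] + size[1] - 1e-12 &
      nodes[, 2] > origin[2] + 1e-12 &
      nodes[, 2] < origin[2] + size[2] - 1e-12 &
      nodes[, 3] > origin[3] + 1e-12 &
      nodes[, 3] < origin[3] + size[3] - 1e-12
    h <- min(size / n)
    nodes[interior, ] <- nodes[interior, ] +
      matrix(runif(3 * sum(interior), -jitter * h, jitter * h),
             ncol = 3)
  }
  tets <- lattice_kuhn_tets(n)
  m <- tet_mesh(nodes, tets)
  vols <- tet_volumes(m)
  flip <- which(vols < 0)
  if (length(flip)) {
    m$tets[flip, c(3, 4)] <- m$tets[flip, c(4, 3)]
  }
  m
}

# 6 tets per cell along vertex-ordered paths from corner 000 to 111;
# conforming across neighbouring cells without parity bookkeeping.
lattice_kuhn_tets <- function(n) {
  id <- function(ijk) {
    ijk[, 1] + (n[1] + 1L) * (ijk[, 2] + (n[2] + 1L) * ijk[, 3]) + 1L
  }
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- as.matrix(expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1),
                                 k = 0:(n[3] - 1)))
  blocks <- vector("list", 6L)
  for (p in seq_len(6)) {
    axstep <- diag(3)[perms[p, ], , drop = FALSE]
    v0 <- cells
    v1 <- sweep(v0, 2, axstep[1, ], "+")
    v2 <- sweep(v1, 2, axstep[2, ], "+")
    v3 <- sweep(v2, 2, axstep[3, ], "+")
    blocks[[p]] <- cbind(id(v0), id(v1), id(v2), id(v3))
  }
  tets <- matrix(0L, nrow(cells) * 6L, 4L)
  for (p in seq_len(6)) {
    tets[seq(p, by = 6L, length.out = nrow(cells)), ] <- blocks[[p]]
  }
  tets
}
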