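#' Parameters of the synthetic head/airway phantom
#'
#' The phantom stands in for patient anatomy so the whole planning pipeline
#' is exercisable without imaging data: a soft-tissue block containing a
#' vertical airway tube with an hourglass (velopharyngeal-type)
#' constriction, rigid jaw patches on the anterior boundary, a fixed
#' posterior (skull) boundary, and landmarks that put the palatal plane at
#' the top of the airway.
#'
#' Default dimensions give roughly 20k elements so that a nonlinear solve
#' completes in well under a minute; all of them are free parameters.
#'
#' @param block_mm block dimensions (lateral, anterior-posterior, vertical)
#'   in mm.
#' @param tube_radius_mm nominal airway radius (mm).
#' @param constriction_radius_mm waist radius r_c of the constriction (mm);
#'   must be smaller than the nominal radius (equal = no constriction).
#' @param constriction_z_mm waist height above the tube bottom (mm);
#'   default: 65% of the tube length (velopharyngeal position).
#' @param constriction_extent_mm axial half-extent of the constriction (mm).
#' @param tube_length_mm airway length (mm); must fit inside the block.
#' @param h_mm lattice resolution (mm).
#' @param seed integer seed recorded in the bundle (the generator itself is
#'   deterministic).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(block_mm = c(64, 64, 88),
                           tube_radius_mm = 12,
                           constriction_radius_mm = 6,
                           constriction_z_mm = NULL,
                           constriction_extent_mm = 12,
                           tube_length_mm = 80,
                           h_mm = 4,
                           seed = 1L) {
  block_mm <- rep(block_mm, length.out = 3)
  stopifnot(all(block_mm > 0), tube_radius_mm > 0, h_mm > 0,
            tube_length_mm > 0, constriction_extent_mm > 0)
  if (constriction_radius_mm > tube_radius_mm) {
    stop("constriction radius must not exceed the nominal tube radius")
  }
  if (tube_length_mm > block_mm[3]) {
    stop("airway tube longer than the block")
  }
  if (is.null(constriction_z_mm)) constriction_z_mm <- 0.65 * tube_length_mm
  if (constriction_z_mm < 0 || constriction_z_mm > tube_length_mm) {
    stop("constriction lies outside the tube")
  }
  structure(list(block_mm = block_mm, tube_radius_mm = tube_radius_mm,
                 constriction_radius_mm = constriction_radius_mm,
                 constriction_z_mm = constriction_z_mm,
                 constriction_extent_mm = constriction_extent_mm,
                 tube_length_mm = tube_length_mm, h_mm = h_mm,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

phantom_radius_profile <- function(params) {
  z0 <- (params$block_mm[3] - params$tube_length_mm) / 2
  zc <- z0 + params$constriction_z_mm
  r0 <- params$tube_radius_mm
  rc <- params$constriction_radius_mm
  w <- params$constriction_extent_mm
  function(z) {
    r <- rep(r0, length(z))
    inside <- abs(z - zc) <= w
    r[inside] <- r0 - (r0 - rc) * cos(pi * (z[inside] - zc) / (2 * w))^2
    r
  }
}

#' Generate the head/airway phantom
#'
#' Builds the tet mesh (conforming 6-tet lattice subdivision with airway
#' cells removed as a void), the anterior face-skin surface (vertices
#' coincide with mesh nodes), the analytic watertight airway surface, the
#' landmark set, and the standard node sets: `maxilla_surface` (anterior-
#' superior patch), `mandible_surface` (anterior-inferior patch),
#' `fixed_skull` (posterior face), `face_skin`, `airway_wall`.
#' Deterministic: identical params give identical bundles.
#'
#' @param params a [phantom_params].
#' @return An object of class `phantom_bundle` with elements `tet_mesh`,
#'   `face_surface`, `airway_surface`, `landmarks`, `params`.
#' @export
make_head_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  L <- params$block_mm
  h <- params$h_mm
  n <- pmax(2L, as.integer(round(L / h)))
  origin <- c(-L[1] / 2, -L[2] / 2, 0)
  mesh <- fixture_tet_block(size = L, n = n, origin = origin)

  z0 <- (L[3] - params$tube_length_mm) / 2
  z1 <- z0 + params$tube_length_mm
  prof <- phantom_radius_profile(params)
  # remove airway cells: tets whose centroid lies inside the tube
  cent <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
             mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  rad <- sqrt(cent[, 1]^2 + cent[, 2]^2)
  in_void <- cent[, 3] >= z0 & cent[, 3] <= z1 & rad < prof(cent[, 3])
  tets <- mesh$tets[!in_void, , drop = FALSE]
  keep_nodes <- sort(unique(as.integer(tets)))
  remap <- integer(nrow(mesh$nodes))
  remap[keep_nodes] <- seq_along(keep_nodes)
  nodes <- mesh$nodes[keep_nodes, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4)

  tol <- 1e-9
  x <- nodes[, 1]; y <- nodes[, 2]; z <- nodes[, 3]
  ymax <- origin[2] + L[2]; ymin <- origin[2]
  anterior <- abs(y - ymax) < tol
  sets <- list(
    fixed_skull = which(abs(y - ymin) < tol),
    face_skin = which(anterior),
    maxilla_surface = which(anterior & z >= 0.55 * L[3] & z <= 0.80 * L[3] &
                              abs(x) <= 0.30 * L[1]),
    mandible_surface = which(anterior & z >= 0.20 * L[3] & z <= 0.45 * L[3] &
                               abs(x) <= 0.30 * L[1])
  )
  m <- tet_mesh(nodes, tets, region = rep("soft_tissue", nrow(tets)),
                node_sets = sets)
  # airway wall: boundary nodes that are not on the outer box
  bnd <- boundary_surface(m)
  bnd_nodes <- sort(unique(as.integer(bnd$faces)))
  on_box <- abs(x - origin[1]) < tol | abs(x - (origin[1] + L[1])) < tol |
    abs(y - ymin) < tol | abs(y - ymax) < tol |
    abs(z - 0) < tol | abs(z - L[3]) < tol
  m$node_sets$airway_wall <- setdiff(bnd_nodes, which(on_box))
  for (s in names(m$node_sets)) {
    if (!length(m$node_sets[[s]])) stop("phantom node set empty: ", s)
  }

  # anterior face sheet, vertices = face_skin nodes
  face_surface <- face_sheet_surface(m, sets$face_skin, origin, L, n)

  dz <- min(1, h / 2)
  n_theta <- max(48L, as.integer(ceiling(2 * pi * params$tube_radius_mm / h) * 4L))
  airway_surface <- fixture_tube(
    radius = params$tube_radius_mm, length = params$tube_length_mm,
    n_theta = n_theta, dz = dz, z0 = z0, profile = prof, label = "airway")

  z_palatal <- z1
  lms <- landmarks(list(
    ANS = c(0, origin[2] + L[2], z_palatal),
    PNS = c(0, origin[2], z_palatal),
    lateral_left = c(origin[1] + L[1], 0, z_palatal),
    soft_palate_tip = c(0, 0, z0 + 0.45 * params$tube_length_mm),
    epiglottis_tip = c(0, 0, z0 + 0.20 * params$tube_length_mm)
  ))
  structure(list(tet_mesh = m, face_surface = face_surface,
                 airway_surface = airway_surface, landmarks = lms,
                 params = params),
            class = "phantom_bundle")
}

# Triangulated sheet over the anterior (y = ymax) lattice face.
face_sheet_surface <- function(mesh, face_nodes, origin, L, n) {
  pts <- mesh$nodes[face_nodes, , drop = FALSE]
  h1 <- L[1] / n[1]; h3 <- L[3] / n[3]
  ii <- as.integer(round((pts[, 1] - origin[1]) / h1))
  kk <- as.integer(round((pts[, 3] - 0) / h3))
  idx <- matrix(NA_integer_, n[1] + 1, n[3] + 1)
  idx[cbind(ii + 1L, kk + 1L)] <- seq_along(face_nodes)
  faces <- list()
  for (i in seq_len(n[1])) {
    for (k in seq_len(n[3])) {
      a <- idx[i, k]; b <- idx[i + 1, k]; c_ <- idx[i + 1, k + 1]
      d <- idx[i, k + 1]
      if (anyNA(c(a, b, c_, d))) next
      faces[[length(faces) + 1]] <- rbind(c(a, b, c_), c(a, c_, d))
    }
  }
  tri_surface(pts, do.call(rbind, faces), label = "face")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("phantom_bundle\n")
  print(x$tet_mesh)
  print(x$airway_surface)
  invisible(x)
}

#' Synthetic post-surgery ground truth
#'
#' Runs the FE model under the given jaw transforms and returns the
#' deformed face and airway surfaces — a synthetic stand-in for
#' post-surgery scans that makes self-consistency recovery testable. An
#' optional lateral stretch factor widens the deformed airway about the
#' midsagittal plane, emulating the anisotropic lateral widening of the
#' velopharynx that isotropic tissue models under-predict.
#'
#' @param bundle a `phantom_bundle`.
#' @param maxilla_transform,mandible_transform [rigid_transform] objects.
#' @param materials a [material_params].
#' @param lateral_stretch multiplicative widening of the airway surface in
#'   x about the x = 0 plane (1 = none).
#' @param options [solver_options()].
#' @return list with `face_surface`, `airway_surface`, `field`.
#' @export
make_ground_truth_post <- function(bundle, maxilla_transform,
                                   mandible_transform, materials,
                                   lateral_stretch = 1,
                                   options = solver_options()) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  bc <- assemble_dirichlet(bundle$tet_mesh, maxilla_transform,
                           mandible_transform)
  field <- solve_displacement(bundle$tet_mesh, materials, bc, options)
  face_post <- deform_surface(field, bundle$face_surface, bundle$tet_mesh)
  airway_post <- deform_surface(field, bundle$airway_surface,
                                bundle$tet_mesh)
  if (lateral_stretch != 1) {
    airway_post$vertices[, 1] <- lateral_stretch * airway_post$vertices[, 1]
  }
  list(face_surface = face_post, airway_surface = airway_post,
       field = field)
}

#' Write a phantom bundle to a directory
#'
#' Writes the tet mesh (VTK), face and airway surfaces (STL), landmarks
#' (CSV) and parameters (JSON).
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tet_mesh(bundle$tet_mesh, file.path(dir, "phantom.vtk"))
  write_surface(bundle$face_surface, file.path(dir, "face.stl"))
  write_surface(bundle$airway_surface, file.path(dir, "airway.stl"))
  write_landmarks(bundle$landmarks, file.path(dir, "landmarks.csv"))
  jsonlite::write_json(unclass(bundle$params),
                       file.path(dir, "params.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
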