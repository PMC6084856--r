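test_that("surface formats round-trip connectivity and coordinates", {
  cube <- make_fixture("cube")
  expect_equal(nrow(cube$faces), 12L)
  for (fmt in c("stl", "ply", "off")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_surface(cube, path)
    back <- read_surface(path)
    if (fmt == "stl") {
      # STL is a triangle soup: vertex order follows the file, so compare
      # the vertex sets and the geometry itself
      srt <- function(v) v[order(v[, 1], v[, 2], v[, 3]), ]
      expect_equal(srt(back$vertices), srt(cube$vertices),
                   tolerance = 1e-12)
      expect_equal(max(dmin_map(back, cube)$dmin), 0, tolerance = 1e-12)
    } else {
      expect_equal(back$vertices, cube$vertices, tolerance = 1e-12)
      expect_equal(back$faces, cube$faces)
    }
    expect_equal(nrow(back$faces), 12L)
    expect_true(is_watertight(back))
  }
})

test_that("binary STL round-trips within float32 precision", {
  s <- make_fixture("sphere", radius = 7.5, n_theta = 16, n_phi = 8)
  path <- tempfile(fileext = ".stl")
  write_surface(s, path, binary = TRUE)
  back <- read_surface(path)
  expect_equal(nrow(back$faces), nrow(s$faces))
  # float32 mantissa ~ 1e-7 relative
  d <- point_to_surface_distance(back$vertices, s)$distance
  expect_lt(max(d), 1e-5)
})

test_that("truncated and malformed surface files raise I/O errors", {
  path <- tempfile(fileext = ".stl")
  writeLines(c("solid x", "facet normal 0 0 1", "outer loop",
               "vertex 0 0"), path)
  expect_error(read_surface(path), "malformed|truncated")
  expect_error(read_surface(tempfile(fileext = ".stl")), "not found")
  bad_off <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "4 0 1 2 3"), bad_off)
  expect_error(read_surface(bad_off), "non-triangular")
})

test_that("VTK legacy tet meshes round-trip nodes, regions and node sets", {
  m <- small_jittered_block(n = c(3, 3, 3), jitter = 0.1)
  m$region[1:20] <- "bone"
  m$node_sets <- list(maxilla_surface = c(1L, 5L, 9L),
                      fixed_skull = c(2L, 3L))
  path <- tempfile(fileext = ".vtk")
  write_tet_mesh(m, path)
  back <- read_tet_mesh(path)
  expect_equal(back$nodes, m$nodes, tolerance = 1e-14)
  expect_equal(back$tets, m$tets)
  expect_equal(back$region, m$region)
  expect_equal(back$node_sets, m$node_sets)
})

test_that("Gmsh MSH 4.1 tet meshes round-trip", {
  m <- small_jittered_block(n = c(2, 3, 2), jitter = 0.15, seed = 4)
  m$region[seq(2, 20, by = 3)] <- "bone"
  m$node_sets <- list(airway_wall = c(4L, 7L), face_skin = 1:5)
  path <- tempfile(fileext = ".msh")
  write_tet_mesh(m, path)
  back <- read_tet_mesh(path)
  expect_equal(back$nodes, m$nodes, tolerance = 1e-14)
  # element order may be grouped by region; compare as sets with regions
  key <- function(mm) {
    o <- order(mm$tets[, 1], mm$tets[, 2], mm$tets[, 3], mm$tets[, 4])
    list(tets = mm$tets[o, ], region = mm$region[o])
  }
  expect_equal(key(back), key(m))
  expect_equal(back$node_sets, m$node_sets)
})

test_that("single reference tetrahedron survives VTK round-trip", {
  m <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                matrix(1:4, 1), region = "soft_tissue")
  path <- tempfile(fileext = ".vtk")
  write_tet_mesh(m, path)
  back <- read_tet_mesh(path)
  expect_equal(nrow(back$tets), 1L)
  expect_equal(nrow(back$nodes), 4L)
  expect_equal(tet_volumes(back), 1 / 6)
})

test_that("non-tetrahedral element types are rejected as format errors", {
  vtk <- tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "hexes", "ASCII",
               "DATASET UNSTRUCTURED_GRID", "POINTS 8 double",
               apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = " "),
               "CELLS 1 9", "8 0 1 2 3 4 5 6 7", "CELL_TYPES 1", "12"),
             vtk)
  expect_error(read_tet_mesh(vtk), "element types")
  m <- small_jittered_block(n = c(2, 2, 2))
  msh <- tempfile(fileext = ".msh")
  write_tet_mesh(m, msh)
  lines <- readLines(msh)
  lines <- sub("^3 1 4 ", "3 1 5 ", lines) # claim 8-node hexahedra
  writeLines(lines, msh)
  expect_error(read_tet_mesh(msh), "element types")
})

test_that("landmarks round-trip through CSV and JSON and match by name", {
  lms <- landmarks(list(ANS = c(0, 40, 0), PNS = c(0, -10, 0),
                        lateral_left = c(30, 0, 0)))
  for (ext in c(".csv", ".json")) {
    path <- tempfile(fileext = ext)
    write_landmarks(lms, path)
    back <- read_landmarks(path)
    expect_equal(landmark_matrix(back), landmark_matrix(lms),
                 tolerance = 1e-12)
  }
  expect_error(landmarks(list(A = c(0, 0, 0), A = c(1, 1, 1))), "unique")
  expect_error(landmark_point(lms, "nose_tip"), "not found")
})

test_that("validate_mesh flags inverted tets, duplicates and open shells", {
  m <- small_jittered_block(n = c(2, 2, 2))
  expect_true(validate_mesh(m)$ok)
  bad <- m
  bad$tets[1, c(1, 2)] <- bad$tets[1, c(2, 1)]
  rep_ <- validate_mesh(bad)
  expect_false(rep_$ok)
  expect_equal(rep_$n_negative_volumes, 1L)

  cyl_open <- make_fixture("cylinder", radius = 5, length = 10,
                           n_theta = 16, dz = 5)
  # removing the caps opens the shell
  ncap <- nrow(cyl_open$vertices)
  keep <- rowSums(matrix(cyl_open$faces %in% c(ncap - 1L, ncap),
                         ncol = 3)) == 0
  open_shell <- tri_surface(cyl_open$vertices,
                            cyl_open$faces[keep, , drop = FALSE])
  expect_true(is_watertight(cyl_open))
  expect_false(is_watertight(open_shell))
  expect_false(validate_mesh(open_shell)$watertight)

  dup <- tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                           c(0, 0, 0)),
                     rbind(c(1, 2, 3), c(4, 2, 3)))
  expect_equal(validate_mesh(dup)$n_duplicate_vertices, 1L)
})

test_that("solving is refused on meshes with inverted elements", {
  m <- small_jittered_block(n = c(2, 2, 2))
  m$tets[3, c(1, 2)] <- m$tets[3, c(2, 1)]
  bn <- boundary_nodes(m)
  bc <- dirichlet_bc(fixed = bn)
  expect_error(solve_displacement(m, test_materials(), bc),
               "invalid mesh")
})
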