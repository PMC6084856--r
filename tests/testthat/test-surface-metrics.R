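test_that("point-to-triangle distances are exact on simple configurations", {
  tri <- tri_surface(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                     matrix(1:3, 1))
  # point on a vertex
  expect_equal(point_to_surface_distance(c(0, 0, 0), tri)$distance, 0)
  # height h above the interior
  q <- point_to_surface_distance(c(2, 3, 1.7), tri)
  expect_equal(q$distance, 1.7, tolerance = 1e-15)
  expect_equal(q$foot, matrix(c(2, 3, 0), 1), tolerance = 1e-15)
  # beyond an edge: distance to the edge
  expect_equal(point_to_surface_distance(c(-3, 4, 0), tri)$distance, 3)
})

test_that("accelerated distance queries equal the brute-force oracle", {
  set.seed(7)
  s <- make_fixture("sphere", radius = 8, n_theta = 48, n_phi = 24)
  s$vertices <- s$vertices + matrix(rnorm(length(s$vertices), sd = 0.1),
                                    ncol = 3)
  pts <- matrix(runif(3000, -12, 12), ncol = 3)
  fast <- point_to_surface_distance(pts, s, accelerate = TRUE)
  slow <- point_to_surface_distance(pts, s, accelerate = FALSE)
  expect_lt(max(abs(fast$distance - slow$distance)), 1e-12)
  expect_lt(max(abs(fast$foot - slow$foot)), 1e-9)
})

test_that("identical surfaces give an all-zero distance map", {
  s <- make_fixture("sphere", radius = 5, n_theta = 24, n_phi = 12)
  dm <- dmin_map(s, s)
  expect_equal(max(dm$dmin), 0)
})

test_that("parallel plates at gap t give d_min identically t", {
  for (gap in c(0.5, 1.5, 3)) {
    pl <- make_fixture("parallel_plates", gap = gap, size = 20, n = 8)
    dm <- dmin_map(pl$A, pl$B)
    expect_equal(min(dm$dmin), gap, tolerance = 1e-12)
    expect_equal(max(dm$dmin), gap, tolerance = 1e-12)
  }
})

test_that("backward distances dominate where they exceed the forward one", {
  # A: a large flat plate; B: the same plate 0.5 above, with one node
  # pulled far up. The pulled B-node projects onto the middle of A, so the
  # A-node owning that foot point must report the large backward distance.
  pl <- make_fixture("parallel_plates", gap = 0.5, size = 20, n = 8)
  A <- pl$A
  B <- pl$B
  mid <- which.min(rowSums(B$vertices[, 1:2]^2))
  B$vertices[mid, 3] <- 6
  dm <- dmin_map(A, B)
  owner <- which.min(rowSums(sweep(A$vertices[, 1:2, drop = FALSE], 2,
                                   B$vertices[mid, 1:2])^2))
  expect_equal(dm$dmin[owner], 6, tolerance = 1e-9)
  expect_lt(dm$forward[owner], dm$dmin[owner]) # forward alone underestimates
  expect_gte(min(dm$dmin - dm$forward), 0)
})

test_that("per-node d_min never falls below the unidirectional distance", {
  set.seed(12)
  s1 <- make_fixture("sphere", radius = 6, n_theta = 20, n_phi = 10)
  s2 <- make_fixture("sphere", radius = 6.8, n_theta = 16, n_phi = 9)
  s2$vertices <- s2$vertices + matrix(c(0.5, -0.3, 0.2),
                                      nrow(s2$vertices), 3, byrow = TRUE)
  dm <- dmin_map(s1, s2)
  expect_gte(min(dm$dmin - dm$forward), 0)
})

test_that("the map scales with the geometry and is rigid-invariant", {
  # jittered spheres: symmetric fixtures have equidistant-vertex ties whose
  # backward assignment flips under rotation round-off
  set.seed(6)
  s1 <- make_fixture("sphere", radius = 4, n_theta = 18, n_phi = 9)
  s2 <- make_fixture("sphere", radius = 5, n_theta = 14, n_phi = 8)
  s1$vertices <- s1$vertices + matrix(rnorm(length(s1$vertices), sd = 0.05),
                                      ncol = 3)
  s2$vertices <- s2$vertices + matrix(rnorm(length(s2$vertices), sd = 0.05),
                                      ncol = 3)
  dm <- dmin_map(s1, s2)
  # uniform scaling
  s1s <- s1; s1s$vertices <- 2.5 * s1$vertices
  s2s <- s2; s2s$vertices <- 2.5 * s2$vertices
  dms <- dmin_map(s1s, s2s)
  expect_equal(dms$dmin, 2.5 * dm$dmin, tolerance = 1e-9)
  # a common rigid motion
  T1 <- rigid_transform(rotation_z(33), translation = c(5, -2, 8),
                        center = c(1, 1, 1))
  dmr <- dmin_map(apply_transform(T1, s1), apply_transform(T1, s2))
  expect_equal(dmr$dmin, dm$dmin, tolerance = 1e-9)
})

test_that("relevance masking selects nodes by displacement magnitude", {
  n <- 50
  u <- matrix(0.05 / sqrt(3), n, 3)
  expect_false(any(relevance_mask(u)))          # uniform 0.05 mm
  u2 <- matrix(0.2 / sqrt(3), n, 3)
  expect_true(all(relevance_mask(u2)))          # uniform 0.2 mm
  u3 <- rbind(matrix(0.5, n / 2, 3), matrix(0, n / 2, 3))
  m <- relevance_mask(u3)
  expect_equal(which(m), 1:(n / 2))
})

test_that("masked summaries use sample statistics over masked nodes only", {
  dm <- structure(list(dmin = c(1, 2, 3, 0, 0), forward = rep(0, 5),
                       backward = rep(0, 5), mask = rep(TRUE, 5)),
                  class = "distance_map")
  s_all <- summarize_distance_map(dm)
  dm2 <- mask_distance_map(dm, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  s_masked <- summarize_distance_map(dm2)
  expect_equal(s_masked$mean, 2)
  expect_equal(s_masked$sd, 1)
  expect_equal(s_masked$n_masked, 3L)
  expect_false(isTRUE(all.equal(s_all$mean, s_masked$mean)))
  dm3 <- mask_distance_map(dm, rep(FALSE, 5))
  expect_error(summarize_distance_map(dm3), "empty relevance mask")
  dm4 <- mask_distance_map(dm, rep(c(7, 7, 7, 0, 0) > 0, 1))
  expect_equal(summarize_distance_map(mask_distance_map(
    structure(list(dmin = rep(7, 4), mask = rep(TRUE, 4)),
              class = "distance_map"), rep(TRUE, 4)))$sd, 0)
})

test_that("distance maps export as PLY with per-vertex scalars", {
  s <- make_fixture("sphere", radius = 3, n_theta = 12, n_phi = 6)
  dm <- dmin_map(s, s)
  path <- tempfile(fileext = ".ply")
  write_distance_map(dm, s, path)
  back <- read_surface(path)
  expect_equal(back$scalars$dmin, dm$dmin, tolerance = 1e-12)
})
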