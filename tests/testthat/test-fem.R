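test_that("Green-Lagrange strain matches its closed forms", {
  expect_equal(green_lagrange_strain(diag(3)), matrix(0, 3, 3))
  expect_equal(green_lagrange_strain(diag(c(1.2, 1, 1))),
               diag(c(0.22, 0, 0)), tolerance = 1e-15)
  # rigid motions carry zero strain (frame indifference of the measure)
  expect_equal(green_lagrange_strain(rotation_z(90)), matrix(0, 3, 3),
               tolerance = 1e-15)
  expect_error(green_lagrange_strain(diag(c(-1, 1, 1))), "inverted")
})

test_that("the generalized Hookean stress evaluates exactly", {
  expect_equal(stress_hooke(matrix(0, 3, 3), E = 5e4, nu = 0.4),
               matrix(0, 3, 3))
  set.seed(1)
  eps <- crossprod(matrix(rnorm(9, sd = 0.05), 3, 3))
  # nu = 0: componentwise proportionality to E
  expect_equal(stress_hooke(eps, E = 7, nu = 0), 7 * eps,
               tolerance = 1e-14)
  # hydrostatic strain alpha*I -> E*alpha/(1-2nu) * I
  expect_equal(stress_hooke(0.01 * diag(3), E = 1, nu = 0.25),
               0.02 * diag(3), tolerance = 1e-14)
  # equivalence with the Lame form lambda tr(eps) I + 2 mu eps
  E <- 15e3; nu <- 0.45
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  expect_equal(stress_hooke(eps, E, nu),
               lam * sum(diag(eps)) * diag(3) + 2 * mu * eps,
               tolerance = 1e-9)
  expect_error(stress_hooke(eps, E = 1, nu = 0.5), "singular")
  expect_error(material_params(list(soft_tissue = list(E = 1, nu = 0.5))),
               "nu")
})

test_that("element forces vanish at rest and under rigid motion", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  z <- element_force_tangent(X, matrix(0, 4, 3), E = 1e3, nu = 0.3)
  expect_equal(max(abs(z$force)), 0)
  R <- rotation_z(35)
  u_rigid <- X %*% t(R) + matrix(c(0.2, -0.4, 0.7), 4, 3, byrow = TRUE) - X
  zr <- element_force_tangent(X, u_rigid, E = 1e3, nu = 0.3)
  expect_lt(max(abs(zr$force)), 1e-9)
})

test_that("the consistent tangent matches central finite differences", {
  set.seed(33)
  X <- rbind(c(0, 0, 0), c(1.1, 0.1, 0), c(-0.2, 0.9, 0.1), c(0, 0.2, 1.2))
  u <- matrix(rnorm(12, sd = 0.02), 4, 3)
  ft <- element_force_tangent(X, u, E = 1e3, nu = 0.35)
  h <- 1e-6
  Kfd <- matrix(0, 12, 12)
  for (j in 1:12) {
    node <- (j - 1) %/% 3 + 1
    comp <- (j - 1) %% 3 + 1
    up <- u; up[node, comp] <- up[node, comp] + h
    um <- u; um[node, comp] <- um[node, comp] - h
    Kfd[, j] <- (element_force_tangent(X, up, 1e3, 0.35)$force -
                   element_force_tangent(X, um, 1e3, 0.35)$force) / (2 * h)
  }
  rel <- max(abs(Kfd - ft$tangent)) / max(abs(ft$tangent))
  expect_lt(rel, 1e-6)
})

test_that("homogeneous deformations pass the patch test on an unstructured mesh", {
  m <- small_jittered_block(n = c(5, 5, 4), jitter = 0.25, seed = 17)
  expect_gte(nrow(m$tets), 500)
  A <- diag(3) + rbind(c(0.04, 0.02, 0), c(0.01, -0.03, 0.02),
                       c(0, 0.01, 0.05))
  bn <- boundary_nodes(m)
  u_b <- m$nodes[bn, ] %*% t(A) - m$nodes[bn, ]
  bc <- dirichlet_bc(nodes = bn, values = u_b)
  f <- solve_displacement(m, test_materials(), bc,
                          solver_options(load_steps = 2, newton_tol = 1e-12))
  exact <- m$nodes %*% t(A) - m$nodes
  expect_lt(max(abs(f$u - exact)), 1e-8)
})

test_that("rigid boundary data produces vanishing nonlinear strain energy", {
  m <- small_jittered_block(n = c(4, 4, 4), jitter = 0.15, seed = 23)
  R <- rotation_z(25)
  u_rig <- m$nodes %*% t(R) +
    matrix(c(0.3, -0.1, 0.2), nrow(m$nodes), 3, byrow = TRUE) - m$nodes
  bn <- boundary_nodes(m)
  bc <- dirichlet_bc(nodes = bn, values = u_rig[bn, ])
  mat <- test_materials()
  f <- solve_displacement(m, mat, bc,
                          solver_options(load_steps = 4, newton_tol = 1e-12))
  W_nl <- strain_energy(m, mat, f)
  W_lin <- strain_energy(m, mat, f, linear = TRUE)
  # the discriminator between the Green-Lagrange model and linear elasticity
  expect_gt(W_lin, 1)
  expect_lt(W_nl / W_lin, 1e-10)
  # interior follows the rigid motion
  expect_lt(max(abs(f$u - u_rig)), 1e-7)
})

test_that("zero boundary data gives the zero field", {
  m <- small_jittered_block(n = c(3, 3, 3))
  bn <- boundary_nodes(m)
  bc <- dirichlet_bc(fixed = bn)
  f <- solve_displacement(m, test_materials(), bc)
  expect_equal(max(abs(f$u)), 0)
})

test_that("the small-strain limit agrees with an independent linear solve", {
  m <- small_jittered_block(n = c(4, 4, 3), jitter = 0.2, seed = 5)
  bn <- boundary_nodes(m)
  n <- nrow(m$nodes)
  delta <- 1e-3
  # non-affine boundary data of magnitude delta
  p <- m$nodes
  u_b <- delta * cbind(p[, 1]^2, p[, 2] * p[, 3], -p[, 3]^2)
  bc <- dirichlet_bc(nodes = bn, values = u_b[bn, ])
  mat <- test_materials()
  f <- solve_displacement(m, mat, bc,
                          solver_options(load_steps = 1, newton_tol = 1e-13))
  # independent route: small-strain equilibrium with the stiffness at u = 0
  lam <- bramax:::lame_constants(1000, 0.3)
  trip <- bramax:::.fem_tangent_triplets(m$nodes, m$tets,
                                         matrix(0, n, 3),
                                         rep(lam$lambda, nrow(m$tets)),
                                         rep(lam$mu, nrow(m$tets)))
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(3 * n, 3 * n))
  cons <- as.integer(t(outer(bn, 1:3, function(a, b) 3L * (a - 1L) + b)))
  free <- setdiff(seq_len(3 * n), cons)
  ufull <- numeric(3 * n)
  ufull[cons] <- as.numeric(t(u_b[bn, ]))
  rhs <- -(K %*% ufull)[free]
  ufull[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  u_lin <- matrix(ufull, n, 3, byrow = TRUE)
  rel <- max(abs(f$u - u_lin)) / max(abs(u_lin))
  expect_lt(rel, 10 * delta)
})

test_that("mirroring mesh and boundary data mirrors the solution", {
  m <- small_jittered_block(n = c(4, 3, 3), jitter = 0.15, seed = 19,
                            size = c(2, 1, 1))
  p <- m$nodes
  bn <- boundary_nodes(m)
  u_b <- 0.02 * cbind(p[, 1] * p[, 3], p[, 2]^2, p[, 3] + p[, 1]^2)
  bc <- dirichlet_bc(nodes = bn, values = u_b[bn, ])
  opts <- solver_options(load_steps = 2, newton_tol = 1e-13)
  f <- solve_displacement(m, test_materials(), bc, opts)
  # reflect the whole problem across the plane x = 1
  m2 <- m
  m2$nodes[, 1] <- 2 - m2$nodes[, 1]
  m2$tets[, c(3, 4)] <- m2$tets[, c(4, 3)] # restore positive orientation
  u_b2 <- cbind(-u_b[, 1], u_b[, 2], u_b[, 3])
  bc2 <- dirichlet_bc(nodes = bn, values = u_b2[bn, ])
  f2 <- solve_displacement(m2, test_materials(), bc2, opts)
  u_expect <- cbind(-f$u[, 1], f$u[, 2], f$u[, 3])
  expect_lt(max(abs(f2$u - u_expect)), 1e-9)
})

test_that("rigid-body nullspace and missing constraints are detected", {
  m <- small_jittered_block(n = c(2, 2, 2))
  expect_error(solve_displacement(m, test_materials(),
                                  dirichlet_bc(fixed = 1L)),
               "nullspace")
})

test_that("surfaces deform by interpolation, exactly for linear fields", {
  m <- small_jittered_block(n = c(4, 4, 4), jitter = 0.1, seed = 2)
  sph <- make_fixture("sphere", radius = 0.3, n_theta = 24, n_phi = 12)
  sph$vertices <- sweep(sph$vertices, 2, c(0.5, 0.5, 0.5), "+")
  A <- diag(3) + rbind(c(0.05, 0.01, 0), c(0, 0.02, 0.03), c(0.01, 0, -0.04))
  bn <- boundary_nodes(m)
  bc <- dirichlet_bc(nodes = bn,
                     values = m$nodes[bn, ] %*% t(A) - m$nodes[bn, ])
  f <- solve_displacement(m, test_materials(), bc,
                          solver_options(load_steps = 1, newton_tol = 1e-13))
  # zero field leaves the surface unchanged
  f0 <- f; f0$u[] <- 0
  expect_equal(deform_surface(f0, sph, m)$vertices, sph$vertices)
  # affine field maps surface vertices affinely (linear-exact interpolation)
  moved <- deform_surface(f, sph, m)
  expect_equal(moved$vertices, sph$vertices %*% t(A), tolerance = 1e-7)
  expect_equal(moved$faces, sph$faces)
  # far-outside vertices raise a containment error
  far <- sph
  far$vertices[1, ] <- c(50, 50, 50)
  expect_error(deform_surface(f, far, m), "outside")
})

test_that("advancement widens the phantom constriction anteriorly", {
  b <- make_head_phantom(small_phantom_params())
  tr <- build_bra_transforms(bra_plan(mxp_cm = 0.4, mdp_cm = 0.8))
  bc <- assemble_dirichlet(b$tet_mesh, tr$maxilla, tr$mandible)
  f <- solve_displacement(b$tet_mesh, material_params(), bc,
                          solver_options(load_steps = 2))
  moved <- deform_surface(f, b$airway_surface, b$tet_mesh)
  # anterior airway wall at the constriction moves anteriorly (+y)
  v <- b$airway_surface$vertices
  zc <- (b$params$block_mm[3] - b$params$tube_length_mm) / 2 +
    b$params$constriction_z_mm
  sel <- abs(v[, 3] - zc) < 2 & v[, 2] > 0.9 * max(v[abs(v[, 3] - zc) < 2, 2])
  expect_gt(min(moved$vertices[sel, 2] - v[sel, 2]), 0)
})

test_that("constriction-area prediction contracts under mesh refinement", {
  run_at <- function(h) {
    pp <- phantom_params(block_mm = c(32, 32, 40), tube_radius_mm = 8,
                         constriction_radius_mm = 4, tube_length_mm = 32,
                         constriction_extent_mm = 8, h_mm = h)
    b <- make_head_phantom(pp)
    tr <- build_bra_transforms(bra_plan(mxp_cm = 0.4, mdp_cm = 0.8))
    bc <- assemble_dirichlet(b$tet_mesh, tr$maxilla, tr$mandible)
    f <- solve_displacement(b$tet_mesh, material_params(), bc,
                            solver_options(load_steps = 2))
    moved <- deform_surface(f, b$airway_surface, b$tet_mesh)
    plane <- palatal_plane(b$landmarks)
    prof <- partition_regions(slice_airway(moved, plane), b$landmarks)
    narrowest_section(prof, "VPX")$area_cm2
  }
  a8 <- run_at(8)
  a4 <- run_at(4)
  a2 <- run_at(2)
  # first-order (staircase-boundary) convergence: successive refinements
  # change the prediction less than the previous level did
  expect_lt(abs(a4 - a2), abs(a8 - a4))
})
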