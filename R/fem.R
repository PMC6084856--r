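#' Material parameters per region
#'
#' Isotropic elastic constants of the generalized Hookean soft-tissue law:
#' Young's modulus E (Pa) and Poisson's ratio nu per material region. The
#' law is singular at nu = 0.5 (incompressible limit), so nu must satisfy
#' -1 < nu < 0.5 strictly. Defaults (15 kPa, 0.45) are typical engineering
#' values for bulk facial soft tissue; they are configuration, not solver
#' constants.
#'
#' @param regions named list; each entry a list with elements `E` and `nu`.
#' @return An object of class `material_params`.
#' @export
material_params <- function(regions = list(
                              soft_tissue = list(E = 15e3, nu = 0.45))) {
  for (nm in names(regions)) {
    E <- regions[[nm]]$E
    nu <- regions[[nm]]$nu
    if (!is.numeric(E) || E <= 0) stop("E must be > 0 for region ", nm)
    if (!is.numeric(nu) || nu <= -1 || nu >= 0.5) {
      stop("nu must lie strictly in (-1, 0.5) for region ", nm)
    }
  }
  structure(list(regions = regions), class = "material_params")
}

lame_constants <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' Green-Lagrange strain tensor
#'
#' `eps = (F'F - I) / 2`; exactly zero for any rigid motion (F = R), which
#' is what distinguishes the geometrically nonlinear model from small-strain
#' elasticity.
#'
#' @param F 3 x 3 deformation gradient with det(F) > 0.
#' @return symmetric 3 x 3 strain matrix.
#' @export
green_lagrange_strain <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  if (det(F) <= 0) stop("inverted element: det(F) <= 0")
  (crossprod(F) - diag(3)) / 2
}

#' Generalized Hookean stress
#'
#' Evaluates `sigma(eps) = E/(1+nu) * (eps + nu/(1-2 nu) tr(eps) I)`,
#' equivalently `sigma = 2 mu eps + lambda tr(eps) I` with the Lame
#' constants; taken work-conjugate to the Green-Lagrange strain (second
#' Piola-Kirchhoff role) in the total-Lagrangian formulation.
#'
#' @param eps symmetric 3 x 3 strain matrix.
#' @param E Young's modulus (Pa).
#' @param nu Poisson's ratio, strictly less than 0.5.
#' @return symmetric 3 x 3 stress matrix (Pa).
#' @export
stress_hooke <- function(eps, E, nu) {
  if (nu >= 0.5) stop("nu = 0.5 makes the law singular (division by zero)")
  eps <- as.matrix(eps)
  E / (1 + nu) * (eps + nu / (1 - 2 * nu) * sum(diag(eps)) * diag(3))
}

#' Element internal force and consistent tangent
#'
#' Single-element interface to the total-Lagrangian kernels, mainly for
#' verification: returns the 12-vector of internal nodal forces (gradient of
#' the strain energy with respect to nodal displacements) and the exact
#' 12 x 12 consistent tangent (material + geometric stiffness).
#'
#' @param element_nodes 4 x 3 matrix of reference node positions (mm).
#' @param u 4 x 3 matrix of nodal displacements (mm).
#' @param E,nu material constants.
#' @return list with `force` (length-12, node-major x/y/z) and `tangent`
#'   (12 x 12).
#' @export
element_force_tangent <- function(element_nodes, u, E, nu) {
  lam <- lame_constants(E, nu)
  tets <- matrix(1:4, 1, 4)
  f <- .fem_force(as.matrix(element_nodes), tets, as.matrix(u),
                  lam$lambda, lam$mu)
  trip <- .fem_tangent_triplets(as.matrix(element_nodes), tets,
                                as.matrix(u), lam$lambda, lam$mu)
  K <- matrix(0, 12, 12)
  # force/tangent DOF order: node-major (n1x n1y n1z n2x ...)
  K[cbind(trip$i, trip$j)] <- 0
  for (k in seq_along(trip$i)) {
    K[trip$i[k], trip$j[k]] <- K[trip$i[k], trip$j[k]] + trip$x[k]
  }
  list(force = as.numeric(t(f)), tangent = K)
}

#' Solver options
#'
#' @param load_steps number of proportional load increments (>= 1).
#' @param newton_tol relative residual tolerance per load step.
#' @param max_newton_iters Newton iteration cap per step.
#' @param linear_solver "direct" (sparse factorization via Matrix) is the
#'   only supported choice at present.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(load_steps = 4, newton_tol = 1e-8,
                           max_newton_iters = 30,
                           linear_solver = "direct") {
  stopifnot(load_steps >= 1, newton_tol > 0, max_newton_iters >= 1)
  structure(list(load_steps = as.integer(load_steps),
                 newton_tol = newton_tol,
                 max_newton_iters = as.integer(max_newton_iters),
                 linear_solver = match.arg(linear_solver, "direct")),
            class = "solver_options")
}

#' Solve the nonlinear elastostatic problem
#'
#' Newton-Raphson with proportional load stepping and residual-increase line
#' search on the total-Lagrangian St. Venant-Kirchhoff tetrahedral model.
#' Bone-region elements are removed from the elastic system (bones are
#' rigid; their motion enters through the Dirichlet data), air regions carry
#' no elements.
#'
#' @param mesh a [tet_mesh] that passes [validate_mesh()].
#' @param materials a [material_params] covering every elastic region tag.
#' @param bc a [dirichlet_bc]; at least 6 degrees of freedom must be
#'   constrained (no rigid-body nullspace).
#' @param options a [solver_options].
#' @return An object of class `displacement_field`: list with `u` (n x 3
#'   displacements, mm), `iterations`, `final_residual`, `converged`.
#' @export
solve_displacement <- function(mesh, materials, bc,
                               options = solver_options()) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(bc, "dirichlet_bc"),
            inherits(materials, "material_params"))
  rep_ <- validate_mesh(mesh)
  if (!isTRUE(rep_$ok)) {
    stop("refusing to solve on an invalid mesh (see validate_mesh)")
  }
  elastic <- !(mesh$region %in% c("bone", "air"))
  tets <- mesh$tets[elastic, , drop = FALSE]
  region <- mesh$region[elastic]
  if (!nrow(tets)) stop("mesh has no elastic elements")
  for (r in unique(region)) {
    if (is.null(materials$regions[[r]])) {
      stop("no material parameters for region: ", r)
    }
  }
  lam <- vapply(region, function(r) {
    lame_constants(materials$regions[[r]]$E, materials$regions[[r]]$nu)$lambda
  }, numeric(1))
  mu <- vapply(region, function(r) {
    lame_constants(materials$regions[[r]]$E, materials$regions[[r]]$nu)$mu
  }, numeric(1))

  n <- nrow(mesh$nodes)
  cons_nodes <- c(bc$nodes, bc$fixed)
  target <- rbind(bc$values, matrix(0, length(bc$fixed), 3))
  if (anyDuplicated(cons_nodes)) stop("conflicting Dirichlet constraints")
  cons_dofs <- as.integer(t(outer(cons_nodes, 1:3,
                                  function(a, b) 3L * (a - 1L) + b)))
  if (length(cons_dofs) < 6) {
    stop("rigid-body nullspace: fewer than 6 constrained DOFs")
  }
  free_dofs <- setdiff(seq_len(3L * n), cons_dofs)
  is_free <- logical(3L * n)
  is_free[free_dofs] <- TRUE
  dof_map <- integer(3L * n)
  dof_map[free_dofs] <- seq_along(free_dofs)

  u <- matrix(0, n, 3)
  total_iters <- 0L
  final_res <- NA_real_
  chol_sym <- NULL # symbolic factorization, reused (constant pattern)
  for (s in seq_len(options$load_steps)) {
    frac <- s / options$load_steps
    u[cons_nodes, ] <- frac * target
    ref_res <- NULL
    for (it in seq_len(options$max_newton_iters)) {
      f <- .fem_force(mesh$nodes, tets, u, lam, mu)
      r_free <- as.numeric(t(f))[free_dofs]
      rn <- sqrt(sum(r_free^2))
      if (is.null(ref_res)) ref_res <- max(rn, 1e-300)
      final_res <- rn / ref_res
      if (rn < options$newton_tol * ref_res || rn < 1e-12) break
      trip <- .fem_tangent_triplets(mesh$nodes, tets, u, lam, mu)
      # assemble the free-DOF block directly (no sparse subsetting)
      keep <- is_free[trip$i] & is_free[trip$j]
      Kff <- Matrix::sparseMatrix(i = dof_map[trip$i[keep]],
                                  j = dof_map[trip$j[keep]],
                                  x = trip$x[keep],
                                  dims = rep(length(free_dofs), 2))
      # the consistent tangent is symmetric; CHOLMOD is much faster than LU
      # and fails informatively when the tangent loses positive definiteness
      du <- tryCatch({
        Ks <- Matrix::forceSymmetric(Kff)
        ch <- if (is.null(chol_sym)) {
          Matrix::Cholesky(Ks, LDL = FALSE)
        } else {
          Matrix::update(chol_sym, Ks)
        }
        chol_sym <- ch
        as.numeric(Matrix::solve(ch, -r_free))
      }, error = function(e) tryCatch(
        as.numeric(Matrix::solve(Kff, -r_free)),
        error = function(e2) stop("linear solve failed (singular tangent): ",
                                  conditionMessage(e2))
      ))
      # line search: halve until the residual decreases and no element inverts
      step <- 1
      repeat {
        u_try <- u
        u_flat <- as.numeric(t(u_try))
        u_flat[free_dofs] <- u_flat[free_dofs] + step * du
        u_try <- matrix(u_flat, n, 3, byrow = TRUE)
        ok_det <- .fem_min_det(mesh$nodes, tets, u_try) > 0
        if (ok_det) {
          f_try <- .fem_force(mesh$nodes, tets, u_try, lam, mu)
          rn_try <- sqrt(sum(as.numeric(t(f_try))[free_dofs]^2))
          if (rn_try < rn || step < 1 / 64) {
            u <- u_try
            break
          }
        } else if (step < 1 / 64) {
          stop("element inversion could not be avoided by line search")
        }
        step <- step / 2
      }
      total_iters <- total_iters + 1L
    }
    if (final_res >= options$newton_tol && it == options$max_newton_iters) {
      stop(sprintf(
        "Newton did not converge in load step %d (relative residual %.3e)",
        s, final_res))
    }
  }
  structure(list(u = u, iterations = total_iters,
                 final_residual = final_res, converged = TRUE,
                 elastic_elements = which(elastic)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mags <- sqrt(rowSums(x$u^2))
  cat(sprintf(
    "displacement_field: %d nodes, |u| max %.4f mm, %d Newton iterations (rel. residual %.2e)\n",
    nrow(x$u), max(mags), x$iterations, x$final_residual))
  invisible(x)
}

#' Total strain energy of a displacement field
#'
#' Evaluates either the geometrically nonlinear energy (Green-Lagrange
#' strain) or the small-strain linear-elastic energy of the same field;
#' the ratio of the two under rigid boundary data is the standard frame-
#' indifference diagnostic.
#'
#' @param mesh a [tet_mesh].
#' @param materials a [material_params].
#' @param u n x 3 displacement matrix or a `displacement_field`.
#' @param linear if TRUE use the small-strain energy.
#' @return scalar energy (Pa mm^3 = micro-Joule).
#' @export
strain_energy <- function(mesh, materials, u, linear = FALSE) {
  if (inherits(u, "displacement_field")) u <- u$u
  elastic <- !(mesh$region %in% c("bone", "air"))
  tets <- mesh$tets[elastic, , drop = FALSE]
  region <- mesh$region[elastic]
  lam <- vapply(region, function(r)
    lame_constants(materials$regions[[r]]$E,
                   materials$regions[[r]]$nu)$lambda, numeric(1))
  mu <- vapply(region, function(r)
    lame_constants(materials$regions[[r]]$E,
                   materials$regions[[r]]$nu)$mu, numeric(1))
  .fem_energy(mesh$nodes, tets, as.matrix(u), lam, mu, linear)
}

#' Deform a surface by a displacement field
#'
#' Surface vertices coinciding with mesh nodes move exactly by the nodal
#' displacement; other vertices are interpolated with the barycentric
#' coordinates of their best containing tetrahedron (the linear shape
#' functions extend continuously across element boundaries, so vertices
#' within `containment_tol` of the mesh are handled by the same formula).
#'
#' @param field a `displacement_field` from [solve_displacement()].
#' @param surface a [tri_surface].
#' @param mesh the [tet_mesh] the field lives on.
#' @param containment_tol how far (in barycentric units) a vertex may lie
#'   outside its best tetrahedron before a containment error is raised.
#' @return the deformed [tri_surface] (connectivity unchanged).
#' @export
deform_surface <- function(field, surface, mesh, containment_tol = 2) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(surface, "tri_surface"), inherits(mesh, "tet_mesh"))
  loc <- .locate_in_tets(surface$vertices, mesh$nodes, mesh$tets)
  if (min(loc$quality) < -containment_tol) {
    stop(sprintf(
      "surface vertex outside the mesh (worst barycentric coordinate %.3f)",
      min(loc$quality)))
  }
  conn <- mesh$tets[loc$tet, , drop = FALSE]
  disp <- loc$bary[, 1] * field$u[conn[, 1], , drop = FALSE] +
    loc$bary[, 2] * field$u[conn[, 2], , drop = FALSE] +
    loc$bary[, 3] * field$u[conn[, 3], , drop = FALSE] +
    loc$bary[, 4] * field$u[conn[, 4], , drop = FALSE]
  out <- surface
  out$vertices <- surface$vertices + disp
  out
}

#' Interpolate a displacement field at arbitrary points
#'
#' @inheritParams deform_surface
#' @param points n x 3 matrix of query points (mm).
#' @return n x 3 matrix of interpolated displacements (mm).
#' @export
interpolate_displacement <- function(field, points, mesh,
                                     containment_tol = 2) {
  s <- tri_surface(points, matrix(integer(0), 0, 3))
  loc <- .locate_in_tets(s$vertices, mesh$nodes, mesh$tets)
  if (min(loc$quality) < -containment_tol) {
    stop("query point outside the mesh")
  }
  conn <- mesh$tets[loc$tet, , drop = FALSE]
  loc$bary[, 1] * field$u[conn[, 1], , drop = FALSE] +
    loc$bary[, 2] * field$u[conn[, 2], , drop = FALSE] +
    loc$bary[, 3] * field$u[conn[, 3], , drop = FALSE] +
    loc$bary[, 4] * field$u[conn[, 4], , drop = FALSE]
}
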