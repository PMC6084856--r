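#' Bimaxillary rotation advancement plan
#'
#' Encodes the planned rigid jaw displacements of a BRA procedure: maxillary
#' impaction (Mxi, superior repositioning), maxillary protrusion (Mxp,
#' anterior advancement), mandibular protrusion (Mdp) and a counter-clockwise
#' rotation of the maxillo-mandibular complex. Magnitudes are given in cm to
#' match the clinical convention of planning tables; impaction is stored as
#' an unsigned magnitude and applied superiorly (+z).
#'
#' @param mxi_cm maxillary impaction magnitude (cm).
#' @param mxp_cm maxillary protrusion (cm).
#' @param mdp_cm mandibular protrusion (cm).
#' @param ccw_deg counter-clockwise rotation (degrees) about the +x axis as
#'   seen from the patient's right (sagittal view); default 0.
#' @param maxilla_center,mandible_center rotation centers (mm). The maxilla
#'   center models the osteotomy design that shifts the rotation pivot to
#'   the middle of the maxilla.
#' @return An object of class `bra_plan`.
#' @export
bra_plan <- function(mxi_cm = 0, mxp_cm = 0, mdp_cm = 0, ccw_deg = 0,
                     maxilla_center = c(0, 0, 0),
                     mandible_center = c(0, 0, 0)) {
  stopifnot(mxi_cm >= 0, mxp_cm >= 0, mdp_cm >= 0, is.finite(ccw_deg),
            length(maxilla_center) == 3, length(mandible_center) == 3)
  structure(list(mxi_cm = mxi_cm, mxp_cm = mxp_cm, mdp_cm = mdp_cm,
                 ccw_deg = ccw_deg,
                 maxilla_center = as.numeric(maxilla_center),
                 mandible_center = as.numeric(mandible_center)),
            class = "bra_plan")
}

#' @export
print.bra_plan <- function(x, ...) {
  cat(sprintf(
    "bra_plan: Mxi %.1f cm, Mxp %.1f cm, Mdp %.1f cm, CCW %.1f deg\n",
    x$mxi_cm, x$mxp_cm, x$mdp_cm, x$ccw_deg))
  invisible(x)
}

rotation_about_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), -sin(th),
           0, sin(th), cos(th)), 3, 3, byrow = TRUE)
}

#' Rigid jaw transforms from a BRA plan
#'
#' The maxilla rotates counter-clockwise about its (shifted) center and is
#' then translated anteriorly by the protrusion and superiorly by the
#' impaction; the mandible (anterior fragment, splinted to the maxilla)
#' undergoes the same rotation about its own center plus its protrusion.
#' Plan magnitudes in cm are converted to mm.
#'
#' @param plan a [bra_plan].
#' @return list with elements `maxilla` and `mandible`, both
#'   [rigid_transform] objects. A zero plan yields two identity transforms.
#' @export
build_bra_transforms <- function(plan) {
  stopifnot(inherits(plan, "bra_plan"))
  R <- rotation_about_x(plan$ccw_deg)
  list(
    maxilla = rigid_transform(
      rotation = R,
      translation = c(0, 10 * plan$mxp_cm, 10 * plan$mxi_cm),
      center = plan$maxilla_center),
    mandible = rigid_transform(
      rotation = R,
      translation = c(0, 10 * plan$mdp_cm, 0),
      center = plan$mandible_center)
  )
}

#' Dirichlet boundary conditions
#'
#' Per-node prescribed displacement vectors plus named zero-displacement
#' sets. `nodes` and `values` list the non-trivially constrained nodes;
#' `fixed` lists nodes clamped to zero.
#'
#' @param nodes integer vector of constrained node indices.
#' @param values numeric length(nodes) x 3 matrix of prescribed
#'   displacements (mm).
#' @param fixed integer vector of zero-displacement node indices.
#' @return An object of class `dirichlet_bc`.
#' @export
dirichlet_bc <- function(nodes = integer(0),
                         values = matrix(0, 0, 3),
                         fixed = integer(0)) {
  nodes <- as.integer(nodes)
  values <- matrix(as.numeric(values), ncol = 3)
  fixed <- sort(unique(as.integer(fixed)))
  if (length(nodes) != nrow(values)) {
    stop("values must have one row per constrained node")
  }
  if (anyDuplicated(nodes)) stop("node constrained twice with values")
  both <- intersect(nodes, fixed)
  if (length(both)) {
    conflict <- rowSums(abs(values[match(both, nodes), , drop = FALSE])) > 0
    if (any(conflict)) stop("conflicting constraints on nodes: ",
                            paste(both[conflict], collapse = ", "))
    keep <- !(nodes %in% both)
    nodes <- nodes[keep]
    values <- values[keep, , drop = FALSE]
  }
  structure(list(nodes = nodes, values = values, fixed = fixed),
            class = "dirichlet_bc")
}

#' Assemble Dirichlet BCs from jaw transforms
#'
#' Nodes in the `maxilla_surface` and `mandible_surface` sets receive the
#' displacement of their rigid jaw transform, `u = T(p) - p`; `fixed_skull`
#' nodes are clamped to zero; all other nodes remain free.
#'
#' @param mesh a [tet_mesh] with non-empty node sets `maxilla_surface`,
#'   `mandible_surface` and `fixed_skull`.
#' @param maxilla_transform,mandible_transform [rigid_transform] objects.
#' @return a [dirichlet_bc].
#' @export
assemble_dirichlet <- function(mesh, maxilla_transform, mandible_transform) {
  req <- c("maxilla_surface", "mandible_surface", "fixed_skull")
  for (s in req) {
    if (is.null(mesh$node_sets[[s]]) || !length(mesh$node_sets[[s]])) {
      stop("mesh is missing required non-empty node set: ", s)
    }
  }
  mx <- mesh$node_sets$maxilla_surface
  md <- mesh$node_sets$mandible_surface
  if (length(intersect(mx, md))) {
    stop("maxilla_surface and mandible_surface node sets overlap")
  }
  pmx <- mesh$nodes[mx, , drop = FALSE]
  pmd <- mesh$nodes[md, , drop = FALSE]
  umx <- apply_transform(maxilla_transform, pmx) - pmx
  umd <- apply_transform(mandible_transform, pmd) - pmd
  dirichlet_bc(nodes = c(mx, md), values = rbind(umx, umd),
               fixed = mesh$node_sets$fixed_skull)
}
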