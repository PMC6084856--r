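# Shared small geometry builders for the test suite.

small_jittered_block <- function(n = c(5, 5, 4), jitter = 0.2, seed = 11,
                                 size = c(1, 1, 1)) {
  make_fixture("unit_tet_block", size = size, n = n, jitter = jitter,
               seed = seed)
}

test_materials <- function(E = 1000, nu = 0.3) {
  material_params(list(soft_tissue = list(E = E, nu = nu)))
}

boundary_nodes <- function(mesh) {
  sort(unique(as.integer(boundary_surface(mesh)$faces)))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# Small phantom for pipeline-level tests (seconds-scale FE solves).
small_phantom_params <- function(seed = 1L) {
  phantom_params(block_mm = c(40, 40, 56), tube_radius_mm = 8,
                 constriction_radius_mm = 4, tube_length_mm = 48,
                 h_mm = 5, seed = seed)
}

small_run_config <- function(seed = 1L, ...) {
  run_config(seed = seed, phantom = small_phantom_params(seed),
             plan = bra_plan(mxi_cm = 0.2, mxp_cm = 0.4, mdp_cm = 0.8),
             solver = solver_options(load_steps = 2), ...)
}

extdata <- function(name) {
  system.file("extdata", name, package = "bramax", mustWork = TRUE)
}
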