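# Shared fixtures: small meshes, boundary-condition helpers, and a lazy
# cache so expensive scenario solves run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# uniaxial-stress bar conditions: axial displacement prescribed on the end
# faces, lateral contraction free, minimal rigid-body pins
bar_bcs <- function(mesh, delta) {
  bb <- mesh$geometry$bbox
  tol <- 1e-9
  list(
    bc_dirichlet(function(n) abs(n[, 1] - bb["x", 1]) < tol, 1, 0),
    bc_dirichlet(function(n) abs(n[, 1] - bb["x", 2]) < tol, 1, delta),
    bc_dirichlet(function(n) abs(n[, 1] - bb["x", 1]) < tol &
                   abs(n[, 2] - bb["y", 1]) < tol &
                   abs(n[, 3] - bb["z", 1]) < tol, 2:3, 0),
    bc_dirichlet(function(n) abs(n[, 1] - bb["x", 1]) < tol &
                   abs(n[, 2] - bb["y", 2]) < tol &
                   abs(n[, 3] - bb["z", 1]) < tol, 3, 0))
}

# minimal rigid-body pins for a fully free block (3-2-1 scheme)
free_block_bcs <- function(mesh) {
  bb <- mesh$geometry$bbox
  tol <- 1e-9
  corner <- function(xv, yv) function(n)
    abs(n[, 1] - xv) < tol & abs(n[, 2] - yv) < tol &
    abs(n[, 3] - bb["z", 1]) < tol
  list(
    bc_dirichlet(corner(bb["x", 1], bb["y", 1]), 1:3, 0),
    bc_dirichlet(corner(bb["x", 2], bb["y", 1]), 2:3, 0),
    bc_dirichlet(corner(bb["x", 1], bb["y", 2]), 3, 0))
}

scenario_cached <- function(name, ...) {
  cached(paste0("scenario_", name), run_scenario(name, ...))
}
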