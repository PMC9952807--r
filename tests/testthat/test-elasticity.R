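mat1 <- list(pdms = material(1e6, 0.49))

test_that("uniaxial bar reproduces the analytic uniform strain state", {
  m <- box_mesh(c(2, 1, 1), c(4, 3, 3))
  f <- solve_elasticity(m, mat1,
                        load_case("applied_stretch", applied_strain = 0.15),
                        bcs = bar_bcs(m, 0.3))
  eps <- probe_strain(f, c(1.1, 0.4, 0.6))
  expect_equal(eps[1, 1], 0.15, tolerance = 1e-12)
  expect_equal(eps[2, 2], -0.49 * 0.15, tolerance = 1e-10)
  expect_equal(eps[3, 3], -0.49 * 0.15, tolerance = 1e-10)
  expect_lt(max(abs(eps[upper.tri(eps)])), 1e-12)
  # the state is uniform: all elements carry the same tensor
  expect_lt(max(abs(sweep(f$strain, 2, f$strain[1, ]))), 1e-10)
})

test_that("zero load yields an identically zero field", {
  m <- box_mesh(c(1, 1, 1), c(3, 3, 3))
  f <- solve_elasticity(m, mat1,
                        load_case("applied_stretch", applied_strain = 0),
                        bcs = list(bc_dirichlet("clamped_end", 1:3, 0),
                                   bc_dirichlet("moving_end", 1, 0)))
  expect_equal(max(abs(f$displacement)), 0)
  expect_equal(max(abs(f$strain)), 0)
})

test_that("stored strains satisfy the discrete symmetric-gradient identity", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  m <- mesh_geometry(geo, 0.35)
  f <- solve_elasticity(m, load = load_case("applied_stretch",
                                            applied_strain = 0.1))
  recomputed <- strainavoid:::element_strains(m, f$displacement, f$active)
  expect_equal(f$strain[f$active, ], recomputed[f$active, ],
               tolerance = 1e-12)
})

test_that("free block under isotropic eigenstrain contracts stress-free", {
  m <- box_mesh(c(1, 1, 1), c(3, 3, 3), region = "hydrogel")
  cc <- 0.07
  f <- solve_elasticity(m, list(hydrogel = material(21e3, 0.2)),
                        load_case("self_condensation",
                                  contraction_magnitude = cc,
                                  seeding_mode = "hydrogel_3d"),
                        bcs = free_block_bcs(m))
  eps <- probe_strain(f, c(0.5, 0.5, 0.5))
  expect_equal(eps, diag(-cc, 3), tolerance = 1e-10)
  expect_lt(max(abs(f$strain[, 1:3] + cc)), 1e-9)
  expect_lt(max(abs(f$strain[, 4:6])), 1e-9)
})

test_that("solution energy decreases monotonically under refinement", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  ld <- load_case("applied_stretch", applied_strain = 0.15)
  en <- vapply(c(0.45, 0.3, 0.2), function(r) {
    m <- mesh_geometry(geo, r, refine_grooves = FALSE)
    solve_elasticity(m, load = ld)$stiffness_energy
  }, 0)
  expect_true(all(diff(en) < 0))
})

test_that("sidewall spring limits recover the bonded and detached solutions", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  m <- mesh_geometry(geo, 0.3)
  probe <- representative_probe(geo)
  sol <- function(k) solve_elasticity(m, load = load_case(
    "self_condensation", contraction_magnitude = 0.2,
    sidewall_spring_stiffness = k, seeding_mode = "hydrogel_3d"))
  eps_stiff <- probe_strain(sol(1e13), probe)
  # bonded reference: sidewall displacement pinned
  bcs_bonded <- c(default_bcs(m, load_case(
    "self_condensation", contraction_magnitude = 0.2,
    sidewall_spring_stiffness = 0, seeding_mode = "hydrogel_3d"))[-2],
    list(bc_dirichlet("groove_sidewall", 1:3, 0)))
  f_bonded <- solve_elasticity(m, load = load_case(
    "self_condensation", contraction_magnitude = 0.2,
    sidewall_spring_stiffness = 0, seeding_mode = "hydrogel_3d"),
    bcs = bcs_bonded)
  eps_bonded <- probe_strain(f_bonded, probe)
  expect_equal(eps_stiff, eps_bonded, tolerance = 1e-3)
  # k -> 0 recovers the fully detached (free sidewall) solution
  eps0 <- probe_strain(sol(0), probe)
  eps_small <- probe_strain(sol(1e-3), probe)
  expect_equal(eps_small, eps0, tolerance = 1e-6)
  # transverse contraction is monotone in the spring stiffness
  tr <- vapply(c(0, 1e7, 1e8, 1e9, 1e13),
               function(k) probe_strain(sol(k), probe)[2, 2], 0)
  expect_true(all(diff(tr) > 0))   # less negative as support stiffens
})

test_that("mirror-symmetric loads give mirror-symmetric strain fields", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  m <- mesh_geometry(geo, 0.3)
  f <- solve_elasticity(m, load = load_case("applied_stretch",
                                            applied_strain = 0.15))
  ymid <- sum(geo$bbox["y", ]) / 2
  p1 <- representative_probe(geo) + c(0.1, 0.08, 0)
  p2 <- p1; p2[2] <- 2 * ymid - p1[2]
  e1 <- probe_strain(f, p1); e2 <- probe_strain(f, p2)
  # mirror in y: normal components equal, xy and yz shears flip sign
  flip <- diag(c(1, -1, 1))
  expect_equal(e1, flip %*% e2 %*% flip,
               tolerance = 1e-8 * max(abs(e1)), ignore_attr = TRUE)
})

test_that("probing outside the mesh or the active subdomain errors", {
  m <- box_mesh(c(1, 1, 1), c(2, 2, 2))
  f <- solve_elasticity(m, mat1,
                        load_case("applied_stretch", applied_strain = 0.1),
                        bcs = bar_bcs(m, 0.1))
  expect_error(probe_strain(f, c(2, 0.5, 0.5)), "outside")
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "none")
  mg <- mesh_geometry(geo, 0.3)
  fg <- solve_elasticity(mg, load = load_case("applied_stretch",
                                              applied_strain = 0.1))
  expect_error(probe_strain(fg, c(0.7, 0.35, 1.9)), "void")
})

test_that("invalid load and material specifications are rejected", {
  expect_error(load_case("applied_stretch"), "exactly one")
  expect_error(load_case("self_condensation"), "contraction_magnitude")
  expect_error(material(-1, 0.3), "positive")
  expect_error(material(1e5, 0.5), "between 0 and 0.5")
  m <- box_mesh(c(1, 1, 1), c(2, 2, 2), region = "hydrogel")
  expect_error(solve_elasticity(m, mat1,
                                load_case("applied_stretch",
                                          applied_strain = 0.1)),
               "no material")
})
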