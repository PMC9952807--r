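test_that("single-region solid meshes conformingly with full tagging", {
  m <- box_mesh(c(1, 1, 1), c(2, 2, 2))
  expect_equal(nrow(m$elems), 8)
  expect_true(all(m$region == "pdms"))
  # exterior facets of a 2x2x2 cube: 4 per face x 6 faces
  expect_equal(nrow(m$boundary), 24)
  expect_true(all(m$boundary$tag %in%
                    c("clamped_end", "moving_end", "free")))
  expect_equal(mesh_volume(m), 1)
})

test_that("every element has one region and every exterior facet one tag", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  m <- mesh_geometry(geo, 0.3)
  expect_false(any(is.na(m$region)))
  expect_true(all(m$region %in% c("pdms", "hydrogel", "cell_layer")))
  expect_false(any(is.na(m$boundary$tag)))
  # each exterior facet appears exactly once
  expect_false(any(duplicated(m$boundary[, c("elem", "side")])))
  # region interfaces at groove walls are recorded
  expect_true(all(c("groove_sidewall", "groove_bottom") %in%
                    m$interfaces$tag))
})

test_that("mesh volume equals the analytic solid volume", {
  geo <- chamber_geometry()   # unstructured chamber
  for (res in c(2, 1)) {
    m <- mesh_geometry(geo, res, refine_grooves = FALSE)
    v_analytic <- 20 * 10 * 2 + 20 * (5 + 0.1) * 8
    expect_lt(abs(mesh_volume(m) / v_analytic - 1), 0.01)
  }
  # grooved, seeded unit cell: bbox volume (notch filled by hydrogel)
  geo3 <- chamber_geometry(domain = "unit_cell",
                           groove_axis = "parallel_to_stretch",
                           seeding = "hydrogel_3d")
  m3 <- mesh_geometry(geo3, 0.3)
  expect_equal(mesh_volume(m3), 1.4 * 0.7 * 2, tolerance = 1e-12)
})

test_that("groove refinement bounds the element size in groove regions", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  m <- mesh_geometry(geo, 0.3, refine_grooves = TRUE)
  hs <- strainavoid:::elem_sizes(m)
  in_groove <- m$region == "hydrogel"
  expect_lte(max(hs[in_groove, ]), 0.1 + 1e-12)
  # grooved (hydrogel-filled) chamber honours the same bound; a short
  # chamber keeps the refined mesh small
  geoc <- chamber_geometry(chamber_length = 4,
                           groove_axis = "perpendicular_to_stretch",
                           seeding = "hydrogel_3d")
  mc <- mesh_geometry(geoc, 0.5, refine_grooves = TRUE)
  hsc <- strainavoid:::elem_sizes(mc)
  in_groove <- mc$region == "hydrogel"
  expect_true(any(in_groove))
  expect_lte(max(hsc[in_groove, ]), 0.1 + 1e-12)
})

test_that("refining the resolution increases the element count", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  n1 <- nrow(mesh_geometry(geo, 0.4, refine_grooves = FALSE)$elems)
  n2 <- nrow(mesh_geometry(geo, 0.2, refine_grooves = FALSE)$elems)
  expect_gt(n2, n1)
})

test_that("mirror symmetry about the groove midplane maps tags onto themselves", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  m <- mesh_geometry(geo, 0.3)
  ymid <- sum(geo$bbox["y", ]) / 2
  ctr <- with(m$cell_index, cbind(
    (m$grid$x[ix] + m$grid$x[ix + 1]) / 2,
    (m$grid$y[iy] + m$grid$y[iy + 1]) / 2,
    (m$grid$z[iz] + m$grid$z[iz + 1]) / 2))
  key <- function(p, r) paste(signif(p[, 1], 9), signif(p[, 2], 9),
                              signif(p[, 3], 9), r)
  mirrored <- ctr
  mirrored[, 2] <- 2 * ymid - ctr[, 2]
  expect_setequal(key(ctr, m$region), key(mirrored, m$region))
})

test_that("VTK and MSH exports round-trip the mesh", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  m <- mesh_geometry(geo, 0.35)
  tf <- tempfile(fileext = ".msh")
  write_msh(m, tf)
  back <- read_msh(tf)
  expect_equal(nrow(back$nodes), nrow(m$nodes))
  expect_equal(unname(back$nodes), unname(m$nodes), tolerance = 1e-9)
  expect_equal(back$region, m$region)
  expect_equal(back$elems, m$elems, ignore_attr = TRUE)

  tv <- tempfile(fileext = ".vtk")
  write_vtk(m, tv)
  ln <- readLines(tv)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", ln)))
  expect_equal(sum(grepl("^CELL_TYPES", ln)), 1)
  unlink(c(tf, tv))
})
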