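test_that("unknown scenarios are rejected with the canonical list", {
  expect_error(run_scenario("diagonal_42"), "canonical")
  expect_error(run_config(scenarios = "nope"), "canonical")
  expect_error(run_config(scenarios = character(0)), "empty")
})

test_that("calibration hits its targets on the 3D groove unit cell", {
  geo <- chamber_geometry(domain = "unit_cell",
                          groove_axis = "parallel_to_stretch",
                          seeding = "hydrogel_3d")
  mesh <- mesh_geometry(geo, 0.3)
  probe <- representative_probe(geo)
  k <- calibrate_sidewall_stiffness(mesh, fraction = 0.5)
  sol <- function(kk) solve_elasticity(mesh, load = load_case(
    "self_condensation", contraction_magnitude = 0.2,
    sidewall_spring_stiffness = kk, seeding_mode = "hydrogel_3d"))
  ratio <- probe_strain(sol(k), probe)[2, 2] /
    probe_strain(sol(0), probe)[2, 2]
  expect_equal(ratio, 0.5, tolerance = 0.02)
  cm <- calibrate_contraction(mesh, target = 0.15,
                              sidewall_spring_stiffness = k)
  f <- solve_elasticity(mesh, load = load_case(
    "self_condensation", contraction_magnitude = cm,
    sidewall_spring_stiffness = k, seeding_mode = "hydrogel_3d"))
  eps <- probe_strain(f, probe)[1:2, 1:2]
  peak <- -min(eigen(eps, symmetric = TRUE)$values)
  expect_equal(peak, 0.15, tolerance = 1e-6)
})

test_that("predicted angle sweeps monotonically with contraction strength", {
  res <- scenario_cached("3d_parallel")
  cal <- res$calibration
  sweep <- c(0.02, 0.35, 0.7, 1.3, 2.5) * cal$contraction_magnitude
  angles <- vapply(sweep, function(cm)
    run_scenario("3d_parallel", contraction_magnitude = cm,
                 sidewall_spring_stiffness =
                   cal$sidewall_spring_stiffness)$prediction$angle, 0)
  # from stretch-dominated (90 deg) toward groove-dominated (0 deg); the
  # angle sits at exactly 90 until the contraction cue is strong enough to
  # create an interior maximum, then decreases
  expect_true(all(diff(angles) <= 1e-9))
  expect_lt(angles[length(angles)] - angles[1], 0)
  expect_gte(angles[1], 80)
  expect_lt(angles[length(angles)], 30)
  # the default calibration lies inside the sweep
  expect_gt(res$prediction$angle, angles[length(angles)])
  expect_lt(res$prediction$angle, angles[1])
})

test_that("static variants isolate the condensation cue", {
  res <- run_scenario("3d_parallel_static")
  expect_null(res$stretch_field)
  expect_equal(res$prediction$angle, 0)
})

test_that("the report bundle is complete and reproducible", {
  out1 <- tempfile("report1"); out2 <- tempfile("report2")
  cfg1 <- run_config(scenarios = c("3d_parallel", "2d_perpendicular"),
                     resolution = 0.35, output_dir = out1)
  cfg2 <- run_config(scenarios = c("3d_parallel", "2d_perpendicular"),
                     resolution = 0.35, output_dir = out2)
  r1 <- run_report(cfg1)
  r2 <- run_report(cfg2)
  expect_equal(nrow(r1$angles), 2)
  for (fn in c("alignment_angles.csv", "3d_parallel_profile.csv",
               "3d_parallel_orientation.json", "provenance.json")) {
    expect_true(file.exists(file.path(out1, fn)))
  }
  # identical configuration gives byte-identical reports
  a <- readLines(file.path(out1, "alignment_angles.csv"))
  b <- readLines(file.path(out2, "alignment_angles.csv"))
  expect_identical(a, b)
  prov <- jsonlite::read_json(file.path(out1, "provenance.json"))
  expect_true(nzchar(prov$config_hash))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("config files round-trip through YAML and JSON", {
  cfg <- run_config(scenarios = "3d_parallel", applied_strain = 0.15,
                    resolution = 0.4, seed = 7)
  ty <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), ty)
  back <- read_run_config(ty)
  expect_equal(unclass(back), unclass(cfg))
  tj <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), tj, auto_unbox = TRUE)
  backj <- read_run_config(tj)
  expect_equal(backj$scenarios, cfg$scenarios)
  unlink(c(ty, tj))
})

test_that("expected elongation is the product of length and strain", {
  expect_equal(expected_elongation(15, 0.05), 0.75)
  expect_equal(expected_elongation(10, 0), 0)
  expect_equal(expected_elongation(10, 0.1), 1)
  expect_error(expected_elongation(-1, 0.1), "non-negative")
})
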