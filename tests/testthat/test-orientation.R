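test_that("directional elongation is the quadratic form 1 + u'Eu", {
  expect_equal(directional_elongation(diag(0, 3), c(1, 0, 0)), 1)
  expect_equal(directional_elongation(diag(c(0.15, -0.05, -0.05)),
                                      c(1, 0, 0)), 1.15)
  set.seed(42)
  for (i in 1:20) {
    a <- matrix(rnorm(9, sd = 0.1), 3); eps <- (a + t(a)) / 2
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    brute <- 1 + sum(outer(u, u) * eps)   # explicit double sum
    expect_equal(directional_elongation(eps, u), brute, tolerance = 1e-12)
  }
  expect_error(directional_elongation(diag(0, 3), c(1, 1, 0)), "unit")
})

test_that("the addition law matches its closed-form values", {
  expect_equal(combine_elongations(1, 1, 4), 0.840896415253715,
               tolerance = 1e-12)
  expect_equal(combine_elongations(0.85, 1e6, 4), 0.85, tolerance = 1e-6)
  expect_equal(combine_elongations(1.15, 0.85, 4), 0.796272807435051,
               tolerance = 1e-12)
  expect_error(combine_elongations(-0.1, 1, 4), "positive")
  expect_error(combine_elongations(1, 1, -2), "n must be")
})

test_that("addition-law algebra: symmetry, homogeneity, min bound and limit", {
  set.seed(7)
  for (i in 1:50) {
    a <- runif(1, 0.5, 1.5); b <- runif(1, 0.5, 1.5)
    k <- runif(1, 0.3, 3); n <- runif(1, 1, 8)
    expect_equal(combine_elongations(a, b, n), combine_elongations(b, a, n))
    expect_equal(combine_elongations(k * a, k * b, n),
                 k * combine_elongations(a, b, n), tolerance = 1e-12)
    expect_lte(combine_elongations(a, b, n), min(a, b))
    # strict monotonicity in each argument
    expect_gt(combine_elongations(a + 0.01, b, n),
              combine_elongations(a, b, n))
  }
  # n -> Inf tends to min(a, b): within 1% at n = 64
  for (ab in list(c(1.15, 0.85), c(0.9, 1.4), c(1.02, 1.01))) {
    expect_equal(combine_elongations(ab[1], ab[2], 64), min(ab),
                 tolerance = 0.01)
  }
})

test_that("compression weighs more than extension around e = 1", {
  d <- 0.1
  drop_compress <- combine_elongations(1, 1, 4) -
    combine_elongations(1 - d, 1, 4)
  gain_extend <- combine_elongations(1 + d, 1, 4) -
    combine_elongations(1, 1, 4)
  expect_gt(drop_compress, gain_extend)
  # decreasing e below 1 strictly decreases the combination
  es <- seq(1, 0.7, by = -0.05)
  vals <- combine_elongations(es, 1, 4)
  expect_true(all(diff(vals) < 0))
})

test_that("pure uniaxial stretch drives the cyclic cue perpendicular", {
  m <- box_mesh(c(2, 1, 1), c(4, 3, 3))
  f <- solve_elasticity(m, list(pdms = material(1e6, 0.49)),
                        load_case("applied_stretch", applied_strain = 0.15),
                        bcs = bar_bcs(m, 0.3))
  e_cyc <- cyclic_elongation(f, probe = c(1, 0.5, 0.5))
  ang <- attr(e_cyc, "angles")
  expect_equal(e_cyc[ang == 0], 0.85, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(ang[which.max(e_cyc)], 90)
  pred <- predict_orientation(stretch_field = f, probe = c(1, 0.5, 0.5))
  expect_equal(pred$angle, 90)
  # wrong field kind is rejected
  expect_error(self_elongation(f), "self_condensation")
})

test_that("isotropic contraction of a free block has no preferred direction", {
  m <- box_mesh(c(1, 1, 1), c(3, 3, 3), region = "hydrogel")
  f <- solve_elasticity(m, list(hydrogel = material(21e3, 0.2)),
                        load_case("self_condensation",
                                  contraction_magnitude = 0.1,
                                  seeding_mode = "hydrogel_3d"),
                        bcs = free_block_bcs(m))
  pred <- predict_orientation(condensation_field = f,
                              probe = c(0.5, 0.5, 0.5))
  expect_true(pred$no_preferred_direction)
  expect_true(is.na(pred$angle))
})

test_that("rotating both tensors rotates the prediction equivariantly", {
  # synthetic tensors fed through the angle-grid machinery directly
  params <- combination_params()
  angles <- seq(0, 179.5, by = 0.5)
  eps_c <- diag(c(-0.15, 0.07, 0))     # release-phase cyclic tensor
  # small shear keeps the combined profile unimodal (no degenerate twin)
  eps_s <- matrix(c(0, 0.03, 0, 0.03, -0.12, 0, 0, 0, -0.2), 3, 3)
  prof <- function(ec, es) {
    e1 <- strainavoid:::elongation_curve(ec, angles)
    e2 <- strainavoid:::elongation_curve(es, angles)
    angles[which.max(combine_elongations(e1, e2, 4))]
  }
  base <- prof(eps_c, eps_s)
  for (phi in c(20, 45, 110)) {
    r <- phi * pi / 180
    R <- rbind(c(cos(r), -sin(r), 0), c(sin(r), cos(r), 0), c(0, 0, 1))
    rot <- prof(R %*% eps_c %*% t(R), R %*% eps_s %*% t(R))
    d <- abs(((rot - base - phi) + 90) %% 180 - 90)
    expect_lte(d, params$angle_grid)
  }
})

test_that("coinciding cue directions give exactly that direction", {
  angles <- seq(0, 179.5, by = 0.5)
  eps <- diag(c(-0.1, 0.05, 0))
  e1 <- strainavoid:::elongation_curve(eps, angles)
  e2 <- strainavoid:::elongation_curve(0.5 * eps, angles)
  cmb <- combine_elongations(e1, e2, 4)
  expect_equal(angles[which.max(cmb)], angles[which.max(e1)])
  expect_equal(angles[which.max(cmb)], 90)
})

test_that("linearised and finite-strain elongations agree at 15% strain", {
  eps <- diag(c(0.15, -0.0735, -0.0735))
  us <- rbind(c(1, 0, 0), c(0, 1, 0), c(sqrt(0.5), sqrt(0.5), 0))
  for (i in seq_len(nrow(us))) {
    u <- us[i, ]
    lin <- directional_elongation(eps, u)
    C <- (diag(3) + eps) %*% (diag(3) + eps)   # right Cauchy-Green
    fin <- sqrt(sum(u * (C %*% u)))
    expect_equal(lin, fin, tolerance = 0.01)
  }
})
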