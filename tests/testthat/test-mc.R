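fx <- leksell4c_fixture()

test_that("geometry layout follows the capsule layer stack and pitch", {
  g0 <- build_geometry(fx$capsule, fx$geometry, 0)
  emitter <- g0$regions[g0$regions$role == "emitter", ]
  expect_equal(c(emitter$z0, emitter$z1), c(0.12, 2.12))
  expect_equal(g0$gap, 0.11)

  g1 <- build_geometry(fx$capsule, fx$geometry, 1)
  emitter1 <- g1$regions[g1$regions$role == "emitter", ]
  expect_equal(c(emitter1$z0, emitter1$z1), c(0.12, 2.12) + 2.72)
  expect_equal(sum(g1$regions$role == "active"), 1)

  # pitch equal to the layer sum: zero gap, still valid
  snug <- fx$capsule
  snug$capsule_pitch <- 2.61
  expect_equal(build_geometry(snug, fx$geometry, 2)$gap, 0)

  # pitch below the layer sum names the offending lengths
  tight <- fx$capsule
  tight$capsule_pitch <- 2.5
  expect_error(build_geometry(tight, fx$geometry, 1), "layer sum",
               class = "stacksource_validation")
})

test_that("the focus sits one source-focus distance from the reference midpoint", {
  g <- build_geometry(fx$capsule, fx$geometry, 0)
  midpoint <- 0.12 + 2 / 2
  expect_equal(midpoint - g$focus[3], 40.1)
  expect_error(build_geometry(fx$capsule, unit_geometry(0.5), 0),
               "focus", class = "stacksource_validation")
})

test_that("emission sampling is uniform in the cylinder and seed-reproducible", {
  set.seed(99)
  pts <- sample_emission(1e5, 0.3, 1, 3)
  # axial mean against closed-form uniform moments
  expect_lt(abs(mean(pts[, 3]) - 2), 4 * (2 / sqrt(12)) / sqrt(1e5))
  expect_true(all(pts[, 1]^2 + pts[, 2]^2 <= 0.3^2 + 1e-12))
  expect_true(all(pts[, 3] >= 1 & pts[, 3] <= 3))
  # radial CDF of uniform disc: mean r^2 = R^2/2
  expect_equal(mean(pts[, 1]^2 + pts[, 2]^2), 0.3^2 / 2, tolerance = 0.01)

  set.seed(7); a <- sample_emission(100, 0.3, 1, 3)
  set.seed(7); b <- sample_emission(100, 0.3, 1, 3)
  expect_identical(a, b)

  set.seed(1)
  degenerate <- sample_emission(5, 0, 2, 2)
  expect_equal(unname(degenerate),
               matrix(c(0, 0, 2)[col(degenerate)], ncol = 3))
})

test_that("optical depth reproduces the layer sums and the chord oracle", {
  g1 <- build_geometry(fx$capsule, fx$geometry, 1)
  # axial ray from the emitting capsule front face through one full capsule
  p <- c(0, 0, 2.72)
  tau <- optical_depth(p, g1$focus, g1)
  expect_equal(tau, 0.309876 * 2 + 0.419975 * 0.61, tolerance = 1e-12)
  expect_equal(round(exp(-tau), 3), 0.416)

  # vacuum geometry: zero depth
  vac <- tiny_capsule(mu_zero = TRUE, radius = 0.2)
  gv <- build_geometry(vac, fx$geometry, 2)
  expect_equal(optical_depth(c(0, 0, 6), gv$focus, gv), 0)

  # oblique rays against the dense-sampling chord oracle
  set.seed(5)
  for (i in 1:10) {
    p <- c(runif(1, -0.4, 0.4), runif(1, -0.4, 0.4), runif(1, 3, 6))
    q <- c(runif(1, -0.2, 0.2), runif(1, -0.2, 0.2), -20)
    chord <- oracle_chord(p, q, z0 = 0.12, z1 = 2.12, radius = 0.3)
    capw <- fx$capsule
    capw$active_radius <- 0.3
    gw <- build_geometry(capw, fx$geometry, 0)
    active <- gw$regions[gw$regions$role == "emitter", ]
    tau <- optical_depth(p, q, gw, include_self = TRUE) -
      optical_depth(p, q, gw, include_self = FALSE)
    mu <- linear_attenuation(fx$capsule$active_material)
    expect_equal(tau / mu, chord, tolerance = 5e-3)
  }
})

test_that("tallies are bit-reproducible for identical seed and geometry", {
  a <- estimate_relative_kerma(fx$capsule, fx$geometry, 1, 2e4, seed = 123)
  b <- estimate_relative_kerma(fx$capsule, fx$geometry, 1, 2e4, seed = 123)
  expect_identical(a$mean, b$mean)
  expect_identical(a$standard_error, b$standard_error)
  c <- estimate_relative_kerma(fx$capsule, fx$geometry, 1, 2e4, seed = 124)
  expect_false(identical(a$mean, c$mean))
  expect_error(estimate_relative_kerma(fx$capsule, fx$geometry, 1, 0, seed = 1),
               class = "stacksource_validation")
})

test_that("point-source vacuum limit recovers the inverse-square law", {
  vac <- tiny_capsule(mu_zero = TRUE, radius = 0)
  geo <- unit_geometry(40.1)
  for (n in 1:3) {
    t <- estimate_relative_kerma(vac, geo, n, 100, seed = 17)
    expect_equal(t$mean, (40.1 / (40.1 + n * 2.72))^2, tolerance = 1e-9)
    expect_equal(t$standard_error, 0)
  }
})

test_that("point-source material limit recovers the closed-form product", {
  cap <- tiny_capsule(mu_zero = FALSE, radius = 0)
  geo <- unit_geometry(40.1)
  for (n in 1:3) {
    t <- estimate_relative_kerma(cap, geo, n, 100, seed = 29)
    analytic <- relative_air_kerma(n, cap, geo)$total
    expect_equal(t$mean, analytic, tolerance = 1e-9)
  }
})

test_that("standard error scales as one over the square root of histories", {
  t_small <- estimate_relative_kerma(fx$capsule, fx$geometry, 1, 1e4, seed = 31)
  t_large <- estimate_relative_kerma(fx$capsule, fx$geometry, 1, 1e6, seed = 31)
  ratio <- t_small$standard_error / t_large$standard_error
  expect_gt(ratio, 10 / sqrt(10))   # within a factor-of-10 band around 10
  expect_lt(ratio, 10 * sqrt(10))
})

test_that("extended-source estimate does not exceed the point-source value", {
  for (n in 1:3) {
    t <- estimate_relative_kerma(fx$capsule, fx$geometry, n, 1e5, seed = 41)
    analytic <- relative_air_kerma(n, fx$capsule, fx$geometry)$total
    expect_lte(t$mean, analytic + 3 * t$standard_error)
  }
})

test_that("comparison table reports per-n differences and their maximum", {
  cmp <- mc_vs_analytic_table(fx$capsule, fx$geometry, 0:2, 2e4, seed = 53)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$analytic[1], 1)
  expect_equal(cmp$mc_mean[1], 1)   # reference vs itself, same estimator
  expect_equal(cmp$diff_pp, abs(cmp$analytic - cmp$mc_mean) * 100)
  expect_equal(attr(cmp, "max_diff_pp"), max(cmp$diff_pp))
  expect_error(mc_vs_analytic_table(fx$capsule, fx$geometry, integer(),
                                    100, seed = 1),
               class = "stacksource_validation")
})
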