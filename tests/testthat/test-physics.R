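test_that("decay fraction halves per half-life and rejects negative ages", {
  expect_equal(decay_fraction(0), 1)
  expect_equal(decay_fraction(1), 0.5)
  expect_equal(decay_fraction(2), 0.25)
  expect_equal(decay_fraction(c(0.5, 3)), c(2^-0.5, 0.125))
  expect_error(decay_fraction(-1), class = "stacksource_validation")
})

test_that("linear attenuation is the product of mass coefficient and density", {
  expect_equal(linear_attenuation(material_spec("cobalt", 0.0527, 5.88)),
               0.309876)
  expect_equal(linear_attenuation(material_spec("steel", 0.0535, 7.85)),
               0.419975)
  expect_equal(linear_attenuation(material_spec("transparent", 0, 3)), 0)
})

test_that("correction factors reproduce the published 3-decimal tabulation", {
  fx <- leksell4c_fixture()
  ct <- relative_air_kerma(1:3, fx$capsule, fx$geometry)
  expect_equal(round(ct$attenuation, 3), c(0.416, 0.173, 0.072))
  expect_equal(round(ct$distance, 3), c(0.877, 0.775, 0.690))
  expect_equal(round(ct$total, 3), c(0.365, 0.134, 0.050))
})

test_that("corrections are 1 at n = 0, strictly decreasing, and multiply exactly", {
  fx <- leksell4c_fixture()
  ct <- relative_air_kerma(0:5, fx$capsule, fx$geometry)
  expect_equal(ct$attenuation[1], 1)
  expect_equal(ct$distance[1], 1)
  expect_equal(ct$total[1], 1)
  expect_true(all(diff(ct$attenuation) < 0))
  expect_true(all(diff(ct$distance) < 0))
  expect_true(all(ct$total > 0 & ct$total <= 1))
  expect_identical(ct$total, ct$attenuation * ct$distance)
  expect_error(attenuation_correction(-1, fx$capsule),
               class = "stacksource_validation")
  expect_error(distance_correction(-2, fx$capsule, fx$geometry),
               class = "stacksource_validation")
})

test_that("attenuation follows the power law and the layer-enumeration oracle", {
  for (seed in 1:100) {
    b <- random_scenario(seed)
    a1 <- attenuation_correction(1, b$capsule)
    for (n in 0:4) {
      an <- attenuation_correction(n, b$capsule)
      expect_equal(an, a1^n)
      expect_equal(an, oracle_attenuation(n, b$capsule))
    }
  }
})

test_that("stack output matches the worked combined-pair arithmetic", {
  fx <- leksell4c_fixture()
  mc <- table_transmission(c(0.344, 0.122, 0.043))
  pair <- stack_state(list(source_record("1-1", age = 1),
                           source_record("1-2", age = 1)),
                      fx$capsule, fx$geometry)
  expect_equal(stack_focus_output(pair, mc), 0.672)

  behind_new <- stack_state(list(source_record("2-1", age = 0),
                                 source_record("1-1", age = 1)),
                            fx$capsule, fx$geometry)
  # back-source contribution alone: 50% x 34.4%
  expect_equal(stack_focus_output(behind_new, mc) - 1, 0.172)

  single_new <- stack_state(list(source_record("1-1")), fx$capsule, fx$geometry)
  expect_equal(stack_focus_output(single_new, mc), 1)
  expect_equal(stack_focus_output(stack_state(list(), fx$capsule, fx$geometry),
                                  mc), 0)
})

test_that("stack output is additive and maximal with the strongest source in front", {
  fx <- leksell4c_fixture()
  tr <- analytic_transmission(fx$capsule, fx$geometry)
  set.seed(42)
  for (i in 1:50) {
    acts <- runif(3, 0.1, 1.5)
    ages <- sample(0:3, 3, replace = TRUE)
    mk <- function(ord) {
      stack_state(mapply(function(a, g, j) {
        source_record(sprintf("s%d", j), initial_activity = a, age = g)
      }, acts[ord], ages[ord], seq_along(ord), SIMPLIFY = FALSE),
      fx$capsule, fx$geometry)
    }
    strength <- acts * decay_fraction(ages)
    best <- mk(order(strength, decreasing = TRUE))
    for (k in 1:3) {
      expect_lte(stack_focus_output(mk(sample(3)), tr),
                 stack_focus_output(best, tr) + 1e-12)
    }
    # additivity in sources
    s12 <- mk(1:2)
    expect_equal(stack_focus_output(mk(1:3), tr),
                 stack_focus_output(s12, tr) +
                   strength[3] * tr(2))
  }
})

test_that("transmission table provider errors on unknown positions", {
  mc <- table_transmission(c(0.344, 0.122))
  expect_equal(mc(0), 1)
  expect_equal(mc(c(1, 2)), c(0.344, 0.122))
  expect_error(mc(3), class = "stacksource_validation")
})

test_that("point-source validity threshold is d/h >= 5, inclusive, warning only", {
  fx <- leksell4c_fixture()
  v <- point_source_validity(fx$geometry, fx$capsule)
  expect_equal(v$ratio, 20.05)
  expect_true(v$valid)

  expect_warning(v2 <- point_source_validity(unit_geometry(4), fx$capsule),
                 "point-source")
  expect_equal(v2$ratio, 2)
  expect_false(v2$valid)

  expect_silent(v3 <- point_source_validity(unit_geometry(10), fx$capsule))
  expect_true(v3$valid)
})

test_that("type constructors enforce physical invariants", {
  expect_error(material_spec("m", -0.1, 5), class = "stacksource_validation")
  expect_error(material_spec("m", 0.05, 0), class = "stacksource_validation")
  co <- material_spec("co", 0.0527, 5.88)
  st <- material_spec("st", 0.0535, 7.85)
  expect_error(capsule_spec(co, st, -2, 0.12, 0.49, 2.72),
               class = "stacksource_validation")
  expect_error(unit_geometry(0), class = "stacksource_validation")
  expect_error(source_record("s", initial_activity = -0.5),
               class = "stacksource_validation")
  expect_message(c261 <- capsule_spec(co, st, 2, 0.12, 0.49), "layer sum")
  expect_equal(c261$capsule_pitch, 2.61)
})
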