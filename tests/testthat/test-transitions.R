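test_that("cross-tabulation matches exhaustive enumeration", {
  a <- new_raster(matrix(c(1L, 1L, 2L, 2L), 2, 2), cellsize = 1000,
                  categorical = TRUE)
  b <- new_raster(matrix(c(1L, 2L, 2L, 1L), 2, 2), cellsize = 1000,
                  categorical = TRUE)
  tm <- cross_tabulate(a, b)
  expect_equal(unname(unclass(tm)),
               matrix(c(1, 1, 1, 1), 2, 2))  # by-hand enumeration
  # identical maps give a diagonal matrix
  tmd <- cross_tabulate(a, a)
  expect_equal(unname(unclass(tmd)), diag(c(2, 2)))
  # swapping epochs transposes the flows
  expect_equal(unname(unclass(cross_tabulate(b, a))),
               unname(t(unclass(tm))))
  # nodata in either map removes the cell
  b2 <- b; b2$values[1, 1] <- NA
  expect_equal(sum(cross_tabulate(a, b2)), 3)
  expect_error(cross_tabulate(a, new_raster(matrix(1L, 3, 3),
                                            categorical = TRUE)),
               "same shape")
})

test_that("percent change reproduces the published belt and class changes", {
  expect_equal(round(percent_change(146.3, 73.6), 1), -49.7)
  expect_equal(round(percent_change(257.8, 160.0), 1), -37.9)
  expect_equal(round(percent_change(247.48, 348.56), 2), 40.84)
  expect_equal(round(percent_change(8.37, 37.02), 2), 342.29)
  expect_equal(round(percent_change(16.94, 10.57), 2), -37.60)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 10), "area_t0")
})

test_that("Markov estimation row-normalises flows", {
  expect_equal(unname(unclass(estimate_markov(diag(c(3, 7))))), diag(2))
  flows <- matrix(c(90, 10, 20, 80), 2, 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("a", "b")))
  P <- estimate_markov(flows)
  expect_equal(unname(unclass(P)),
               matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE))
  # empty source class falls back to persistence with a warning
  flows0 <- flows; flows0[2, ] <- 0
  expect_warning(P0 <- estimate_markov(flows0), "identity")
  expect_equal(unname(unclass(P0)[2, ]), c(0, 1))
  expect_equal(unname(rowSums(unclass(P0))), c(1, 1))
})

test_that("scenario multipliers adjust transfers and restore row sums", {
  cls <- c("cropland", "builtup", "unused")
  P <- matrix(c(0.7, 0.2, 0.1,
                0.05, 0.9, 0.05,
                0.1, 0.1, 0.8), 3, 3, byrow = TRUE,
              dimnames = list(cls, cls))
  class(P) <- c("markov_matrix", class(P))
  # empty spec leaves the matrix untouched
  expect_equal(unclass(apply_scenario(P, scenario_spec())), unclass(P))

  spec <- scenario_spec(scenario_rule("cropland", c("builtup", "unused"),
                                      0.8))
  adj <- apply_scenario(P, spec)
  expect_equal(unname(unclass(adj)["cropland", ]), c(0.76, 0.16, 0.08))
  expect_equal(unname(rowSums(unclass(adj))), rep(1, 3), tolerance = 1e-12)

  # a rule targeting its own source never touches the diagonal
  spec2 <- scenario_spec(scenario_rule("unused", cls, 1.3))
  adj2 <- apply_scenario(P, spec2)
  expect_equal(unname(unclass(adj2)["unused", ]), c(0.13, 0.13, 0.74))

  expect_error(apply_scenario(P, scenario_spec(
    scenario_rule("swamp", "builtup", 0.5))), "unknown class")
  expect_error(scenario_rule("a", "b", -1), "positive")
})

test_that("off-diagonal overflow triggers clipping or proportional rescaling", {
  cls <- c("a", "b")
  P <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(cls, cls))
  expect_warning(adj <- apply_scenario(
    P, scenario_spec(scenario_rule("a", "b", 1.5))), "clipped")
  expect_equal(unname(rowSums(unclass(adj))), c(1, 1), tolerance = 1e-12)
  expect_true(all(unclass(adj) >= 0))

  cls3 <- c("a", "b", "c")
  P3 <- matrix(c(0.1, 0.5, 0.4,
                 0.1, 0.8, 0.1,
                 0.1, 0.1, 0.8), 3, 3, byrow = TRUE,
               dimnames = list(cls3, cls3))
  expect_warning(adj3 <- apply_scenario(
    P3, scenario_spec(scenario_rule("a", c("b", "c"), 1.5))), "rescaled")
  expect_equal(unname(rowSums(unclass(adj3))), rep(1, 3),
               tolerance = 1e-12)
  expect_true(all(unclass(adj3) >= 0))
})

test_that("area projection conserves total area and finds the stationary mix", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(project_areas(c(30, 70), diag(2), 5)), c(30, 70))
  expect_equal(unname(project_areas(c(100, 0), P, 1)), c(90, 10))
  long <- project_areas(c(100, 0), P, 200)
  expect_equal(unname(long), c(200 / 3, 100 / 3), tolerance = 1e-6)
  expect_equal(sum(long), 100, tolerance = 1e-9)
  expect_equal(unname(stationary_distribution(P)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_error(project_areas(c(-1, 1), P), "non-negative")
})

test_that("the policy scenario shifts flows in the intended directions", {
  set.seed(41)
  cls <- default_landuse_classes()
  veg <- c("cropland", "forest", "grassland_high", "grassland_low")
  for (i in 1:25) {
    raw <- matrix(rexp(49), 7, 7, dimnames = list(cls, cls))
    diag(raw) <- diag(raw) + 7  # diagonal dominance keeps rows sane
    P <- estimate_markov(raw)
    gov <- apply_scenario(P, government_control_scenario())
    expect_equal(unname(rowSums(unclass(gov))), rep(1, 7),
                 tolerance = 1e-9)
    areas <- runif(7, 10, 100)
    names(areas) <- cls
    nat1 <- project_areas(areas, P, 1)
    gov1 <- project_areas(areas, gov, 1)
    # one-step vegetated -> built-up flow falls under control
    flow_nat <- sum(areas[veg] * unclass(P)[veg, "builtup"])
    flow_gov <- sum(areas[veg] * unclass(gov)[veg, "builtup"])
    expect_lte(flow_gov, flow_nat + 1e-12)
    # unused -> vegetated flow rises
    expect_gte(sum(areas["unused"] * unclass(gov)["unused", veg]),
               sum(areas["unused"] * unclass(P)["unused", veg]) - 1e-12)
    expect_equal(sum(gov1), sum(areas), tolerance = 1e-9 * sum(areas))
    expect_equal(sum(nat1), sum(areas), tolerance = 1e-9 * sum(areas))
  }
})

test_that("zone composition closes to 100% per class", {
  # land-use map equal to the zone map under a 1:1 pairing
  z <- new_raster(matrix(rep(1:3, each = 4), 3, 4, byrow = TRUE),
                  cellsize = 1000, categorical = TRUE)
  zc <- zone_composition(z, z)
  expect_equal(unname(diag(zc)), rep(100, 3))
  expect_true(all(zc[upper.tri(zc) | lower.tri(zc)] == 0))

  # 4-cell toy checked by enumeration
  zones <- new_raster(matrix(c(1L, 1L, 2L, 3L), 2, 2), cellsize = 1000,
                      categorical = TRUE)
  lu <- new_raster(matrix(c(1L, 2L, 1L, 1L), 2, 2), cellsize = 1000,
                   categorical = TRUE)
  zc2 <- zone_composition(zones, lu)
  expect_equal(unname(zc2["1", ]), c(100 / 3, 100 / 3, 100 / 3))
  expect_equal(unname(zc2["2", ]), c(100, 0, 0))
  expect_equal(unname(rowSums(zc2)), rep(100, 2), tolerance = 1e-9)
})
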