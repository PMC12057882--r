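test_that("patch statistics on canonical configurations", {
  # uniform single-class 10x10 raster of 1 km2 cells
  r <- new_raster(matrix(1L, 10, 10), cellsize = 1000, categorical = TRUE)
  ps <- patch_stats(r)
  expect_equal(ps$n_patches, 1L)
  expect_equal(ps$area_km2, 100)
  expect_equal(attr(ps, "total_area_km2"), 100)
  expect_equal(fragmentation(ps$n_patches, ps$area_km2), 0.01)

  # two blocks touching only at a corner
  m <- matrix(2L, 4, 4)
  m[1:2, 1:2] <- 1L
  m[3:4, 3:4] <- 1L
  rr <- new_raster(m, cellsize = 1000, categorical = TRUE)
  expect_equal(patch_stats(rr, connectivity = 4)$n_patches[1], 2L)
  expect_equal(patch_stats(rr, connectivity = 8)$n_patches[1], 1L)

  # 4x4 two-class checkerboard: every cell is its own 4-patch
  cb <- new_raster(outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1L),
                   cellsize = 1000, categorical = TRUE)
  ps4 <- patch_stats(cb, connectivity = 4)
  expect_equal(ps4$n_patches, c(8L, 8L))

  expect_error(patch_stats(new_raster(matrix(NA_integer_, 2, 2),
                                      categorical = TRUE)), "no data")
})

test_that("patch counts agree with the flood-fill oracle on random rasters", {
  set.seed(77)
  for (i in 1:40) {
    r <- rand_landuse(20, 20, K = sample(2:4, 1),
                      p_na = sample(c(0, 0.1), 1))
    for (conn in c(4L, 8L)) {
      ps <- patch_stats(r, connectivity = conn)
      oracle <- flood_fill_counts(r$values, connectivity = conn)
      expect_equal(stats::setNames(ps$n_patches, ps$class),
                   stats::setNames(as.integer(oracle), names(oracle)))
    }
  }
})

test_that("index arithmetic follows the defining formulas", {
  expect_equal(fragmentation(1, 1), 1)
  expect_equal(fragmentation(4, 2), 2)
  expect_equal(separation(1, 100, 100), 0.05)
  # doubling patch count at fixed areas scales separation by sqrt(2)
  expect_equal(separation(8, 20, 100) / separation(4, 20, 100), sqrt(2))
  # growing the type's area at fixed Ni decreases separation
  expect_lt(separation(3, 90, 100), separation(3, 30, 100))

  expect_equal(dominance(1, 1, 1), 1)
  expect_equal(dominance(0, 0, 0), 0)
  expect_equal(dominance(1, 0.5, 0.5), 0.625)

  expect_equal(disturbance(1, 1, 1, "utilized"), 1)
  expect_equal(disturbance(1, 0, 0, "unutilized"), 0.3)
  expect_equal(disturbance(0.2, 0.05, 0.5, "utilized"), 0.215)
  expect_error(disturbance(1, 1, 1, "waste"), "land_status")

  lfi <- fragility(c(construction = 6, forest = 5, arable = 4,
                     grassland = 3, water = 2, desert = 1))
  expect_equal(sum(lfi), 1)
  expect_equal(unname(lfi["construction"]), 6 / 21)
  expect_equal(unname(lfi["desert"]), 1 / 21)
  expect_equal(unname(fragility(rep(2, 5))), rep(0.2, 5))
  expect_error(fragility(c(a = 0, b = 1)), "positive")
})

test_that("splitting a patch raises fragmentation, separation and dominance terms", {
  A <- 100; Ai <- 20; Ni <- 3; Nother <- 5
  expect_lt(fragmentation(Ni, Ai), fragmentation(Ni + 1, Ai))
  expect_lt(separation(Ni, Ai, A), separation(Ni + 1, Ai, A))
  mi_before <- Ni / (Ni + Nother)
  mi_after <- (Ni + 1) / (Ni + 1 + Nother)
  expect_lt(mi_before, mi_after)  # Di grows weakly through Mi
})

test_that("sampling grid closes composition and drops sliver cells", {
  set.seed(13)
  lu <- rand_landuse(25, 25, K = 3, cellsize = 200)  # 5x5 blocks of 1 km
  grid <- build_risk_grid(lu, grid_size = 1000)
  expect_equal(rowSums(grid$comp), grid$cells$A_k, tolerance = 1e-9)
  expect_equal(nrow(grid$cells), 25)

  # knock a corner block below 10% coverage: it must be dropped
  v <- lu$values
  v[1:5, 1:5] <- NA
  v[1, 1] <- 1L
  grid2 <- build_risk_grid(new_raster(v, cellsize = 200,
                                      categorical = TRUE),
                           grid_size = 1000)
  expect_equal(nrow(grid2$cells), 24)
  expect_error(build_risk_grid(lu, grid_size = 1100), "whole multiple")
})

test_that("ERI is the composition-weighted disturbance-fragility product", {
  ind <- data.frame(class = c(1L, 2L), LDI = c(0.4, 0.8),
                    LFI = c(0.25, 0.75))
  grid <- lattice_grid(2, 2)
  grid$comp <- matrix(c(1, 0, 0.5, 0.25,
                        0, 1, 0.5, 0.75), ncol = 2,
                      dimnames = list(NULL, c("1", "2")))
  grid$cells$A_k <- rowSums(grid$comp)
  grid$classes <- c(1L, 2L)
  out <- eri(grid, ind)
  risk <- c(0.4 * 0.25, 0.8 * 0.75)
  expect_equal(out$cells$eri,
               c(risk[1], risk[2], mean(risk),
                 0.25 * risk[1] + 0.75 * risk[2]))
  # convexity bound
  expect_true(all(out$cells$eri <= max(risk) + 1e-12))
  expect_true(all(out$cells$eri >= 0))
})

test_that("a uniform landscape yields identical ERI everywhere", {
  lu <- new_raster(matrix(1L, 20, 20), cellsize = 500, categorical = TRUE)
  grid <- assess_risk(lu, grid_size = 1000,
                      class_names = "cropland",
                      fragility_ranks = c(cropland = 4),
                      land_status = c(cropland = "utilized"))
  expect_equal(length(unique(grid$cells$eri)), 1L)
  ind <- attr(grid, "indices")
  expect_equal(grid$cells$eri[1], ind$LDI * ind$LFI)
})

test_that("risk levels use shared pooled equal-interval breaks", {
  g <- lattice_grid(3, 3)
  g$cells$eri <- c(0, 0.1, 0.2, 0.4, 0.5, 0.6, 0.8, 0.95, 1)
  lv <- classify_risk_levels(g, n_levels = 5)
  expect_equal(lv$cells$risk_level[c(1, 9)], c(1L, 5L))
  expect_equal(lv$cells$risk_level[8], 5L)  # 0.95 in the top bin

  g2 <- g
  g2$cells$eri <- g$cells$eri / 2  # second epoch, lower risk overall
  both <- classify_risk_levels(list(g, g2), n_levels = 5)
  expect_identical(attr(both[[1]], "risk_breaks"),
                   attr(both[[2]], "risk_breaks"))
  expect_equal(max(both[[2]]$cells$risk_level), 3L)

  gc <- g
  gc$cells$eri <- rep(0.3, 9)
  expect_warning(flat <- classify_risk_levels(gc), "constant")
  expect_true(all(flat$cells$risk_level == 1L))
})

test_that("ERI invariants hold across random synthetic landscapes", {
  set.seed(99)
  for (i in 1:15) {
    cfg <- synthetic_config(grid_shape = c(60L, 60L), seed = i,
                            cellsize = 250)
    lu <- generate_landuse_series(cfg, smooth = FALSE)[[1]]
    grid <- assess_risk(lu, grid_size = 1000,
                        class_names = cfg$class_names)
    ind <- attr(grid, "indices")
    expect_equal(rowSums(grid$comp), grid$cells$A_k, tolerance = 1e-9)
    expect_true(all(grid$cells$eri >= 0))
    expect_true(all(grid$cells$eri <= max(ind$LDI * ind$LFI) + 1e-12))
    expect_true(all(ind$Di >= 0 & ind$Di <= 1))
  }
})
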