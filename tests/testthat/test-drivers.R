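make_table <- function(n, effects = c(x1 = 1), noise_sd = 0, seed = 1) {
  set.seed(seed)
  preds <- matrix(runif(n * 9), n,
                  dimnames = list(NULL, paste0("x", 1:9)))
  eff <- rep(0, 9)
  names(eff) <- paste0("x", 1:9)
  eff[names(effects)] <- effects
  data.frame(preds,
             eri = as.numeric(preds %*% eff) + rnorm(n, sd = noise_sd))
}

test_that("split is exact, seeded and idempotent in normalization", {
  tab <- make_table(646)
  out <- normalize_and_split(tab, seed = 4)
  expect_equal(sum(out$split == "train"), 484)
  expect_equal(sum(out$split == "validation"), 162)
  expect_identical(out$split, normalize_and_split(tab, seed = 4)$split)
  expect_false(identical(out$split, normalize_and_split(tab, seed = 5)$split))
  # predictors are within [0,1] wherever training min/max bracket them
  tr <- out[out$split == "train", ]
  expect_true(all(tr$x1 >= 0 & tr$x1 <= 1))
  # a predictor already spanning [0,1] on the training rows is unchanged
  tab2 <- tab
  tab2$x1[1:2] <- c(0, 1)
  out2 <- normalize_and_split(tab2, seed = 99)
  if (all(out2$split[1:2] == "train"))
    expect_equal(out2$x1, tab2$x1)

  tab3 <- tab; tab3$x2 <- 0.7
  expect_warning(out3 <- normalize_and_split(tab3, seed = 1), "constant")
  expect_true(all(out3$x2 == 0))
  expect_error(normalize_and_split(tab[1:10, ]), "at least 20")
})

test_that("R2, RMSE and RPD follow their definitions", {
  y <- c(0, 1, 2, 3); yhat <- c(0.1, 0.9, 2.1, 2.9)
  m <- fit_metrics(y, yhat)
  expect_equal(m$rmse, 0.1)
  expect_equal(m$rpd, sqrt(5) / 0.2)

  # the mean predictor is the R2 = 0, RPD = 1 baseline
  base <- fit_metrics(y, rep(mean(y), 4))
  expect_equal(base$r2, 0)
  expect_equal(base$rpd, 1)
  expect_equal(base$category, "low")

  perfect <- fit_metrics(y, y)
  expect_equal(perfect$rpd, Inf)
  expect_equal(perfect$category, "excellent")
  expect_error(fit_metrics(c(1, 1), c(1, 2)), "constant")
})

test_that("RPD category cutoffs are 1.4 and 2", {
  # construct predictions with a prescribed RPD via the R2 identity
  y <- seq(0, 1, length.out = 50)
  for (target in c(1.2, 1.7, 2.5)) {
    # shrinking towards the mean by 1/target makes RPD exactly target
    yhat <- y - (y - mean(y)) / target
    m <- fit_metrics(y, yhat)
    expect_equal(m$rpd, target, tolerance = 1e-9)
    expect_equal(m$category,
                 if (target >= 2) "excellent"
                 else if (target >= 1.4) "fair" else "low")
  }
})

test_that("RPD and R2 satisfy the 1/sqrt(1-R2) identity", {
  set.seed(12)
  for (i in 1:20) {
    y <- rnorm(30)
    yhat <- y + rnorm(30, sd = runif(1, 0.1, 2))
    m <- fit_metrics(y, yhat)
    expect_equal(m$rpd, 1 / sqrt(1 - m$r2), tolerance = 1e-9)
  }
})

test_that("a noiseless single-predictor signal is recovered almost perfectly", {
  tab <- normalize_and_split(make_table(646, c(x3 = 1), noise_sd = 0),
                             seed = 2)
  fit <- fit_and_validate(tab, grid = driver_grid(num_trees = 50,
                                                  max_depth = c(10, 20),
                                                  mtry = c(3, 6)),
                          seed = 2)
  expect_gt(fit$report$r2, 0.95)
  expect_equal(fit$importance$predictor[which.max(fit$importance$IS)],
               "x3")
})

test_that("a pure-noise response yields near-zero validation R2", {
  tab <- make_table(646, effects = c(x1 = 0), noise_sd = 1, seed = 8)
  tab <- normalize_and_split(tab, seed = 8)
  fit <- fit_and_validate(tab, grid = driver_grid(num_trees = 30,
                                                  max_depth = 6,
                                                  mtry = 3),
                          seed = 8)
  expect_lt(abs(fit$report$r2), 0.1)
})

test_that("grid search is deterministic under a fixed seed", {
  tab <- normalize_and_split(make_table(200, c(x1 = 1), noise_sd = 0.2),
                             seed = 3)
  g <- driver_grid(num_trees = c(10, 30), max_depth = c(3, 10), mtry = 3)
  f1 <- fit_and_validate(tab, grid = g, seed = 5)
  f2 <- fit_and_validate(tab, grid = g, seed = 5)
  expect_identical(f1$best, f2$best)
  expect_identical(f1$cv$cv_rmse, f2$cv$cv_rmse)
  expect_equal(f1$report$r2, f2$report$r2)
})

test_that("OOB permutation importance flags the planted driver", {
  tab <- normalize_and_split(
    make_table(400, c(x2 = 1, x5 = 0.5), noise_sd = 0.1, seed = 6),
    seed = 6)
  train <- tab[tab$split == "train",
               setdiff(names(tab), c("cell_id", "split"))]
  model <- ranger::ranger(eri ~ ., data = train, num.trees = 50,
                          max.depth = 10, mtry = 3, keep.inbag = TRUE,
                          seed = 6, num.threads = 1)
  imp <- importance_scores(model, train, seed = 6)
  expect_equal(sum(imp$relative), 1, tolerance = 1e-12)
  ord <- imp$predictor[order(-imp$IS)]
  expect_equal(ord[1], "x2")
  expect_equal(ord[2], "x5")
  # inert predictors sit in a near-zero band below both signals
  inert <- imp$IS[!imp$predictor %in% c("x2", "x5")]
  expect_true(all(inert < min(imp$IS[imp$predictor %in% c("x2", "x5")])))

  no_oob <- ranger::ranger(eri ~ ., data = train, num.trees = 10,
                           num.threads = 1, seed = 1)
  expect_error(importance_scores(no_oob, train), "keep.inbag")
})

test_that("additive-noise disturbance is available as an alternative", {
  tab <- normalize_and_split(make_table(200, c(x1 = 1), noise_sd = 0.05,
                                        seed = 9), seed = 9)
  train <- tab[tab$split == "train",
               setdiff(names(tab), c("cell_id", "split"))]
  model <- ranger::ranger(eri ~ ., data = train, num.trees = 30,
                          max.depth = 10, mtry = 3, keep.inbag = TRUE,
                          seed = 9, num.threads = 1)
  imp <- importance_scores(model, train, seed = 9, method = "noise")
  expect_equal(imp$predictor[which.max(imp$IS)], "x1")
})
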