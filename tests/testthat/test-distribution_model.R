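test_that("spatial folds partition the cells and keep blocks together", {
  w <- default_world()
  env <- layer_predictors_tbl(w$clim)
  env <- env[env$layer == "mesopelagic", ]
  folds <- build_spatial_folds(env$lat, env$lon, k = 5, block_size = 15,
                               seed = 2)
  expect_equal(length(folds), nrow(env))
  expect_setequal(unique(folds), 1:5)
  # cells sharing a block share a fold
  block <- paste(floor((env$lat + 90) / 15), floor((env$lon + 180) / 15))
  expect_true(all(tapply(folds, block, function(f) length(unique(f))) == 1))
  # approximate balance
  cnt <- table(folds)
  expect_lte(max(cnt) / min(cnt), 2)
})

test_that("five isolated clusters each become one fold", {
  set.seed(1)
  # centres placed well inside distinct 15-degree blocks
  centers <- data.frame(lat = c(-52, -22, 8, 38, 68),
                        lon = c(-112, -52, 8, 68, 128))
  lat <- rep(centers$lat, each = 20) + runif(100, -2, 2)
  lon <- rep(centers$lon, each = 20) + runif(100, -2, 2)
  folds <- build_spatial_folds(lat, lon, k = 5, block_size = 15, seed = 1)
  cl <- rep(1:5, each = 20)
  expect_true(all(tapply(folds, cl, function(f) length(unique(f))) == 1))
  expect_equal(sort(unique(folds)), 1:5)
  # fewer blocks than folds is rejected
  expect_error(build_spatial_folds(runif(50, 0, 5), runif(50, 0, 5),
                                   k = 5, block_size = 15),
               "block")
})

test_that("spatial folds separate test from train more than random folds", {
  set.seed(42)
  lat <- rep(c(-50, 0, 50), each = 40) + runif(120, -5, 5)
  lon <- rep(c(-90, 30, 150), each = 40) + runif(120, -5, 5)
  min_between <- function(folds) {
    d <- as.matrix(stats::dist(cbind(lat, lon)))
    min(vapply(unique(folds), function(f)
      min(d[folds == f, folds != f]), numeric(1)))
  }
  sp <- build_spatial_folds(lat, lon, k = 3, block_size = 20, seed = 1)
  rd <- rhizcensus:::build_random_folds(120, 3, seed = 1)
  expect_gte(min_between(sp), min_between(rd))
})

test_that("a noiseless learnable response is recovered by random CV", {
  tab <- noiseless_table()
  meso <- tab[tab$layer == "mesopelagic", ]
  set.seed(3)
  meso <- meso[sample(nrow(meso), 400), ]
  # response exactly equal to one predictor
  meso$y <- meso$temperature
  cfg <- brt_config(n_repeats = 3, seed = 5)
  a <- cross_validate(meso, "y", config = cfg, scheme = "random")
  expect_gte(a$r2, 0.98)
  expect_true(a$display)
})

test_that("a pure-noise response has no cross-validated skill", {
  tab <- noiseless_table()
  meso <- tab[tab$layer == "mesopelagic", ]
  set.seed(4)
  meso <- meso[sample(nrow(meso), 500), ]
  meso$y <- rnorm(500)
  cfg <- brt_config(n_repeats = 3, seed = 6)
  a <- cross_validate(meso, "y", config = cfg, scheme = "random")
  expect_lt(a$r2, 0.1)
  expect_false(a$display)
})

test_that("cross-validation is reproducible and handles a constant response", {
  tab <- noiseless_table()
  meso <- tab[tab$layer == "mesopelagic", ]
  set.seed(8); meso <- meso[sample(nrow(meso), 150), ]
  cfg <- brt_config(n_repeats = 2, n_trees = 60, seed = 9)
  a1 <- cross_validate(meso, "conc", config = cfg)
  a2 <- cross_validate(meso, "conc", config = cfg)
  expect_identical(a1$r2, a2$r2)
  expect_identical(a1$mean_predicted, a2$mean_predicted)
  meso$flat <- 1
  expect_message(a3 <- cross_validate(meso, "flat", config = cfg),
                 "constant response")
  expect_true(is.na(a3$r2))
})

test_that("global prediction maps have sane mean, SD and CV", {
  tab <- noiseless_table()
  meso <- tab[tab$layer == "mesopelagic", ]
  set.seed(10); train <- meso[sample(nrow(meso), 200), ]
  grid <- meso[1:300, ]
  # single repeat: SD identically zero
  one <- predict_global(train, "conc", grid,
                        config = brt_config(n_repeats = 1, n_trees = 60))
  expect_true(all(one$sd == 0))
  # constant training response: every cell predicts that constant
  train$const <- 3.5
  cst <- predict_global(train, "const", grid,
                        config = brt_config(n_repeats = 2, n_trees = 60))
  expect_equal(cst$mean, rep(3.5, nrow(grid)), tolerance = 1e-6)
  # several repeats: nonnegative means, CV = sd/mean
  many <- predict_global(train, "conc", grid,
                         config = brt_config(n_repeats = 4, n_trees = 60,
                                             seed = 2))
  expect_true(all(many$mean >= 0))
  pos <- many$mean > 0
  expect_equal(many$cv[pos], many$sd[pos] / many$mean[pos])
  expect_error(predict_global(train, "conc", grid[, 1:3],
                              config = brt_config(n_repeats = 1)),
               "lacks predictor")
})

test_that("full-data predictions are invariant to training row order", {
  tab <- noiseless_table()
  meso <- tab[tab$layer == "mesopelagic", ]
  set.seed(11); train <- meso[sample(nrow(meso), 150), ]
  grid <- meso[1:50, ]
  cfg <- brt_config(n_repeats = 1, n_trees = 80, subsample = 1)
  p1 <- predict_global(train, "conc", grid, config = cfg)
  p2 <- predict_global(train[sample(nrow(train)), ], "conc", grid,
                       config = cfg)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-10)
})

test_that("partial dependence reflects what the model uses", {
  tab <- noiseless_table()
  meso <- tab[tab$layer == "mesopelagic", ]
  set.seed(12); train <- meso[sample(nrow(meso), 200), ]
  train$y <- train$temperature          # monotone in temperature only
  cfg <- brt_config(n_repeats = 2, n_trees = 150, seed = 3)
  pd_t <- partial_dependence(train, "y", "temperature", config = cfg)
  # endpoints cover the observed range
  expect_equal(range(pd_t$value), range(train$temperature))
  # monotone up to ensemble noise
  expect_gt(stats::cor(pd_t$value, pd_t$yhat, method = "spearman"), 0.95)
  # an ignored variable yields a (nearly) flat curve
  pd_o <- partial_dependence(train, "y", "oxygen", config = cfg)
  expect_lt(diff(range(pd_o$yhat)), 0.02 * diff(range(pd_t$yhat)))
  expect_error(partial_dependence(train, "y", "nope", config = cfg),
               "not in predictor")
})
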