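# Boosted regression trees: per-group, per-layer models with random and
# spatial-block cross-validation, global mean/SD prediction maps and
# partial-dependence curves.

#' Boosted-regression-tree configuration
#'
#' The fixed hyperparameter set used for every model: learning rate
#' 0.08, maximum tree depth 2, minimum of 1 element per leaf, exactly
#' 500 trees (no early stopping). `n_repeats` seed-replicated ensembles
#' provide the prediction mean and SD; `subsample` (row resampling per
#' tree) is what differentiates the repeats.
#'
#' @param learning_rate Shrinkage per tree (0.08).
#' @param max_depth Maximum tree depth (2).
#' @param min_child_weight Minimum elements per leaf (1).
#' @param n_trees Number of boosting rounds (500).
#' @param n_repeats Ensemble repeats for CV and mapping (20).
#' @param n_folds Cross-validation folds (5).
#' @param block_size Spatial block size in degrees (15).
#' @param subsample Row subsample fraction per tree (0.75).
#' @param seed Base seed; repeat r uses `seed + r`.
#' @return An object of class `rz_brt_config`.
#' @export
brt_config <- function(learning_rate = 0.08, max_depth = 2,
                       min_child_weight = 1, n_trees = 500,
                       n_repeats = 20, n_folds = 5, block_size = 15,
                       subsample = 0.75, seed = 1L) {
  stopifnot(learning_rate > 0, max_depth >= 1, min_child_weight >= 0,
            n_trees >= 1, n_repeats >= 1, n_folds >= 2, block_size > 0,
            subsample > 0, subsample <= 1)
  structure(list(learning_rate = learning_rate, max_depth = max_depth,
                 min_child_weight = min_child_weight, n_trees = n_trees,
                 n_repeats = n_repeats, n_folds = n_folds,
                 block_size = block_size, subsample = subsample,
                 seed = as.integer(seed)),
            class = "rz_brt_config")
}

#' Default predictor set of the model table
#' @return Character vector of predictor column names.
#' @export
brt_predictors <- function() {
  c("temperature", "salinity", "oxygen", "silicate", "phosphate",
    "nitrate", "chl", "bathymetry")
}

fit_brt <- function(x, y, config, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(eta = config$learning_rate,
                  max_depth = config$max_depth,
                  min_child_weight = config$min_child_weight,
                  subsample = config$subsample,
                  objective = "reg:squarederror",
                  nthread = 1, seed = as.integer(seed) %% .Machine$integer.max),
    data = dtrain, nrounds = config$n_trees, verbose = 0)
}

#' Split cells into spatial folds
#'
#' Groups cells into square geographic blocks of `block_size` degrees,
#' then assigns whole blocks to `k` folds greedily (largest block first,
#' into the currently smallest fold, block order seed-shuffled among
#' ties), so cells within one block always share a fold and fold sizes
#' are approximately balanced.
#'
#' @param lat,lon Cell-centre coordinates.
#' @param k Number of folds (default 5).
#' @param block_size Block edge, degrees (default 15).
#' @param seed Seed for the block shuffle.
#' @return Integer fold assignment (one of `1:k` per cell).
#' @export
build_spatial_folds <- function(lat, lon, k = 5, block_size = 15,
                                seed = 1L) {
  if (length(lat) < k) stop("fewer cells than folds")
  block <- paste(floor((lat + 90) / block_size),
                 floor((lon + 180) / block_size))
  blocks <- unique(block)
  if (length(blocks) < k)
    stop("only ", length(blocks), " spatial block(s) for ", k,
         " folds; enlarge the domain or shrink block_size")
  set.seed(as.integer(seed))
  counts <- table(block)[sample(length(blocks))]  # shuffle, then sort
  counts <- counts[order(-as.numeric(counts))]
  fold_of_block <- integer(length(counts))
  names(fold_of_block) <- names(counts)
  fold_sizes <- numeric(k)
  for (b in seq_along(counts)) {
    f <- which.min(fold_sizes)
    fold_of_block[b] <- f
    fold_sizes[f] <- fold_sizes[f] + counts[b]
  }
  unname(fold_of_block[block])
}

build_random_folds <- function(n, k = 5, seed = 1L) {
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(k), n))
}

#' Cross-validate a boosted-regression-tree model
#'
#' For each of `n_repeats` repeats, draws a fresh (seeded) fold
#' assignment -- uniformly at random over observations, or by spatial
#' blocks -- trains on each set of `k - 1` folds and predicts the
#' held-out fold. Predictions are averaged per observation across
#' repeats, and the skill score is the squared Pearson correlation
#' between observed and mean predicted response. Models with a skill
#' above 0.05 under random CV are flagged for display.
#'
#' @param table Model table (one row per cell x layer).
#' @param response Response column name.
#' @param predictors Predictor column names, default [brt_predictors()].
#' @param config [brt_config()].
#' @param scheme `"random"` or `"spatial"`.
#' @return List of class `rz_assessment`: `r2`, `scheme`, `display`
#'   (R2 > 0.05), `observed`, `mean_predicted`, `n`.
#' @export
cross_validate <- function(table, response, predictors = brt_predictors(),
                           config = brt_config(),
                           scheme = c("random", "spatial")) {
  scheme <- match.arg(scheme)
  stopifnot(response %in% names(table), all(predictors %in% names(table)))
  y <- table[[response]]
  if (length(unique(y)) < 2) {
    message("constant response '", response, "': R2 undefined")
    return(structure(list(r2 = NA_real_, scheme = scheme, display = FALSE,
                          observed = y, mean_predicted = rep(NA_real_,
                                                             length(y)),
                          n = length(y)),
                     class = "rz_assessment"))
  }
  x <- table[, predictors, drop = FALSE]
  pred_sum <- numeric(length(y))
  pred_n <- numeric(length(y))
  for (r in seq_len(config$n_repeats)) {
    rep_seed <- config$seed + r
    folds <- switch(scheme,
      random = build_random_folds(length(y), config$n_folds, rep_seed),
      spatial = build_spatial_folds(table$cell_lat, table$cell_lon,
                                    config$n_folds, config$block_size,
                                    rep_seed))
    for (f in sort(unique(folds))) {
      test <- folds == f
      fit <- fit_brt(x[!test, , drop = FALSE], y[!test], config, rep_seed)
      pred_sum[test] <- pred_sum[test] +
        stats::predict(fit, as.matrix(x[test, , drop = FALSE]))
      pred_n[test] <- pred_n[test] + 1
    }
  }
  mean_pred <- pred_sum / pred_n
  r2 <- if (stats::sd(mean_pred) == 0) NA_real_ else
    stats::cor(y, mean_pred)^2
  structure(list(r2 = r2, scheme = scheme,
                 display = isTRUE(r2 > 0.05), observed = y,
                 mean_predicted = mean_pred, n = length(y)),
            class = "rz_assessment")
}

#' @export
print.rz_assessment <- function(x, ...) {
  cat(sprintf("BRT assessment (%s CV, n = %d): R2 = %s%s\n", x$scheme, x$n,
              format(round(x$r2, 3)),
              if (isTRUE(x$display)) " [display]" else ""))
  invisible(x)
}

#' Predict a response on the global environmental grid
#'
#' Trains `n_repeats` models on the full table (differing only in seed
#' and row resampling), predicts every grid cell with each, and returns
#' the per-cell ensemble mean, standard deviation and coefficient of
#' variation. Negative ensemble means are floored at 0 (concentrations
#' are nonnegative).
#'
#' @param table Model table.
#' @param response Response column.
#' @param env_grid data.frame of grid cells carrying all predictor
#'   columns (e.g. from [layer_predictors()] filtered to one layer).
#' @param predictors Predictor columns, default [brt_predictors()].
#' @param config [brt_config()].
#' @return `env_grid` with `mean`, `sd` and `cv` columns appended.
#' @export
predict_global <- function(table, response, env_grid,
                           predictors = brt_predictors(),
                           config = brt_config()) {
  missing <- setdiff(predictors, names(env_grid))
  if (length(missing))
    stop("environmental grid lacks predictor(s): ",
         paste(missing, collapse = ", "))
  x <- as.matrix(table[, predictors, drop = FALSE])
  y <- table[[response]]
  newx <- as.matrix(env_grid[, predictors, drop = FALSE])
  preds <- matrix(NA_real_, nrow(newx), config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    fit <- fit_brt(x, y, config, config$seed + r)
    preds[, r] <- stats::predict(fit, newx)
  }
  m <- pmax(rowMeans(preds), 0)
  s <- apply(preds, 1, stats::sd)
  out <- env_grid
  out$mean <- m
  out$sd <- if (config$n_repeats == 1) 0 else s
  out$cv <- ifelse(m > 0, out$sd / m, NA_real_)
  out
}

#' Partial-dependence curve of one predictor
#'
#' Marginal effect of `variable`: for each value on a grid spanning its
#' observed range, every training row has the variable substituted by
#' that value and the mean prediction over rows and ensemble repeats is
#' recorded.
#'
#' @param table Model table.
#' @param response Response column.
#' @param variable Predictor to profile.
#' @param predictors Predictor set, default [brt_predictors()].
#' @param config [brt_config()].
#' @param grid_n Number of grid points (default 25).
#' @return data.frame with columns `value` and `yhat`.
#' @export
partial_dependence <- function(table, response, variable,
                               predictors = brt_predictors(),
                               config = brt_config(), grid_n = 25) {
  if (!variable %in% predictors) stop("variable not in predictor set")
  x <- as.matrix(table[, predictors, drop = FALSE])
  y <- table[[response]]
  grid <- seq(min(table[[variable]]), max(table[[variable]]),
              length.out = grid_n)
  models <- lapply(seq_len(config$n_repeats), function(r)
    fit_brt(x, y, config, config$seed + r))
  yhat <- vapply(grid, function(v) {
    xv <- x
    xv[, variable] <- v
    mean(vapply(models, function(m) mean(stats::predict(m, xv)), numeric(1)))
  }, numeric(1))
  data.frame(value = grid, yhat = yhat)
}

#' Assess one response under both CV schemes
#'
#' Convenience wrapper producing the per-scheme skill report used by the
#' assessment CSV: random and spatial R2 plus the display flag.
#'
#' @inheritParams cross_validate
#' @return data.frame with `response`, `scheme`, `r2`, `display`, `n`.
#' @export
assess_response <- function(table, response,
                            predictors = brt_predictors(),
                            config = brt_config()) {
  rows <- lapply(c("random", "spatial"), function(s) {
    a <- cross_validate(table, response, predictors, config, s)
    data.frame(response = response, scheme = s, r2 = a$r2,
               display = a$display, n = a$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
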