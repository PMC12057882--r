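#' Normalise predictors and split a driver table
#'
#' Linearly (min-max) normalises every predictor to `[0, 1]`, with the
#' minima and ranges taken from the training rows only, then applied to
#' all rows. The train/validation split is a seeded random draw of
#' `round(train_fraction * n)` rows; the default fraction 484/646 mirrors
#' the customary ~75% split of a 646-point sample. A constant predictor
#' carries no information and is mapped to 0 with a warning.
#'
#' @param table data.frame with predictor columns and a response column.
#' @param train_fraction fraction of rows assigned to training.
#' @param seed RNG seed for the split.
#' @param response name of the response column (default `"eri"`).
#' @return the table with normalised predictors and a `split` column
#'   (`"train"`/`"validation"`).
#' @export
normalize_and_split <- function(table, train_fraction = 484 / 646,
                                seed = 1L, response = "eri") {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 20L) stop("need at least 20 rows", call. = FALSE)
  if (!response %in% names(table))
    stop("response column '", response, "' not found", call. = FALSE)
  preds <- setdiff(names(table), c(response, "cell_id", "split"))
  if (anyNA(table[c(preds, response)]))
    stop("table must be free of missing values", call. = FALSE)
  n <- nrow(table)
  n_train <- round(train_fraction * n)
  if (n_train < 1L || n_train >= n)
    stop("`train_fraction` leaves an empty split", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  split <- rep("validation", n)
  split[idx] <- "train"
  for (p in preds) {
    v <- table[[p]]
    lo <- min(v[split == "train"]); hi <- max(v[split == "train"])
    if (hi - lo <= 0) {
      warning("constant predictor '", p, "' mapped to 0", call. = FALSE)
      table[[p]] <- rep(0, n)
    } else {
      table[[p]] <- (v - lo) / (hi - lo)
    }
  }
  table$split <- split
  attr(table, "response") <- response
  attr(table, "predictors") <- preds
  table
}

#' Hyperparameter grid for the driver regression
#'
#' The reduced default grid keeps exhaustive search affordable:
#' `num_trees` {10..50}, `max_depth` {3..20}, `mtry` {2..8}. The full
#' published-style ranges (trees 5-50 by 1, depth 1-20 by 1, mtry 1-9)
#' can be requested via the arguments.
#'
#' @param num_trees,max_depth,mtry candidate values.
#' @export
driver_grid <- function(num_trees = c(10, 20, 30, 40, 50),
                        max_depth = c(3, 6, 10, 15, 20),
                        mtry = c(2, 4, 6, 8)) {
  expand.grid(num_trees = num_trees, max_depth = max_depth, mtry = mtry,
              KEEP.OUT.ATTRS = FALSE)
}

#' Fit and validate the driver-importance regression
#'
#' Tunes a random-forest regression of the risk response on the driver
#' predictors by exhaustive grid search with k-fold cross-validation on
#' the training rows (lowest mean CV RMSE wins; ties go to the first grid
#' row, so a fixed seed gives identical choices). The winning
#' configuration is refit on all training rows with out-of-bag
#' bookkeeping enabled, scored on the validation rows (R2, RMSE, RPD) and
#' its per-predictor OOB permutation importances computed.
#'
#' @param table output of [normalize_and_split()].
#' @param grid hyperparameter grid ([driver_grid()]).
#' @param folds number of CV folds (default 4).
#' @param seed RNG seed (CV assignment, forests, importance permutations).
#' @param importance_repeats permutation repeats per tree/predictor for
#'   the importance score.
#' @return a `driver_fit`: list with `model`, `best` (chosen row of the
#'   grid), `cv` (grid with mean CV RMSE), `report` (validation metrics),
#'   `importance` (data.frame).
#' @export
fit_and_validate <- function(table, grid = driver_grid(), folds = 4L,
                             seed = 1L, importance_repeats = 1L) {
  stopifnot(is.data.frame(table), "split" %in% names(table))
  response <- attr(table, "response") %||% "eri"
  preds <- attr(table, "predictors") %||%
    setdiff(names(table), c(response, "cell_id", "split"))
  train <- table[table$split == "train", c(preds, response)]
  valid <- table[table$split == "validation", c(preds, response)]
  if (nrow(train) < folds)
    stop("fewer training rows than folds", call. = FALSE)
  grid$mtry <- pmin(grid$mtry, length(preds))
  fml <- stats::as.formula(paste(response, "~ ."))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(train)))
  cv_rmse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- train[fold_id != f, , drop = FALSE]
      te <- train[fold_id == f, , drop = FALSE]
      fit <- ranger::ranger(fml, data = tr,
                            num.trees = grid$num_trees[g],
                            max.depth = grid$max_depth[g],
                            mtry = grid$mtry[g],
                            seed = seed + f, num.threads = 1)
      pr <- stats::predict(fit, data = te, num.threads = 1)$predictions
      errs[f] <- sqrt(mean((pr - te[[response]])^2))
    }
    cv_rmse[g] <- mean(errs)
  }
  best_i <- which.min(cv_rmse)  # ties: first grid row
  best <- grid[best_i, , drop = FALSE]
  model <- ranger::ranger(fml, data = train,
                          num.trees = best$num_trees,
                          max.depth = best$max_depth,
                          mtry = best$mtry,
                          keep.inbag = TRUE, seed = seed,
                          num.threads = 1)
  pred_v <- stats::predict(model, data = valid,
                           num.threads = 1)$predictions
  report <- fit_metrics(valid[[response]], pred_v)
  imp <- importance_scores(model, train, response = response,
                           seed = seed, n_repeats = importance_repeats)
  structure(
    list(model = model, best = best,
         cv = cbind(grid, cv_rmse = cv_rmse),
         report = report, importance = imp,
         response = response, predictors = preds),
    class = "driver_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf(
    "<driver_fit> %d trees, depth %d, mtry %d | validation R2 %.3f, RMSE %.4f, RPD %.2f (%s)\n",
    x$best$num_trees, x$best$max_depth, x$best$mtry,
    x$report$r2, x$report$rmse, x$report$rpd, x$report$category))
  imp <- x$importance[order(-x$importance$relative), ]
  cat("top drivers:",
      paste(sprintf("%s (%.2f)", imp$predictor[seq_len(min(3, nrow(imp)))],
                    imp$relative[seq_len(min(3, nrow(imp)))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Out-of-bag permutation importance
#'
#' Implements the feature importance score
#' `IS = mean over trees of (errOOB2 - errOOB1)`: for each tree,
#' `errOOB1` is its mean squared error on its out-of-bag rows, and
#' `errOOB2` the error after the target predictor's values are disturbed
#' among those same rows. The default disturbance is a within-OOB
#' permutation; `method = "noise"` instead adds Gaussian noise with the
#' predictor's own OOB standard deviation. Scores are reported raw and
#' sum-normalised over their positive parts (relative influence).
#'
#' @param model a `ranger` regression fitted with `keep.inbag = TRUE`.
#' @param data the training data.frame the model was fitted on.
#' @param response response column name.
#' @param seed RNG seed for the permutations.
#' @param n_repeats disturbance repeats averaged per tree/predictor.
#' @param method `"permute"` (default) or `"noise"`.
#' @return data.frame with `predictor`, `IS`, `relative`.
#' @export
importance_scores <- function(model, data, response = "eri", seed = 1L,
                              n_repeats = 1L,
                              method = c("permute", "noise")) {
  method <- match.arg(method)
  if (!inherits(model, "ranger"))
    stop("`model` must be a ranger fit", call. = FALSE)
  if (is.null(model$inbag.counts))
    stop("model lacks OOB bookkeeping; refit with keep.inbag = TRUE",
         call. = FALSE)
  preds <- setdiff(names(data), response)
  n_trees <- model$num.trees
  y <- data[[response]]
  all_pred <- stats::predict(model, data = data, predict.all = TRUE,
                             num.threads = 1)$predictions
  oob <- lapply(model$inbag.counts, function(cnt) which(cnt == 0))
  err1 <- vapply(seq_len(n_trees), function(t) {
    rows <- oob[[t]]
    mean((all_pred[rows, t] - y[rows])^2)
  }, numeric(1))
  set.seed(seed)
  IS <- numeric(length(preds))
  names(IS) <- preds
  for (p in preds) {
    deltas <- matrix(NA_real_, n_trees, n_repeats)
    for (t in seq_len(n_trees)) {
      rows <- oob[[t]]
      if (length(rows) < 2L) next
      for (r in seq_len(n_repeats)) {
        perturbed <- data[rows, preds, drop = FALSE]
        if (method == "permute") {
          perturbed[[p]] <- perturbed[[p]][sample.int(length(rows))]
        } else {
          perturbed[[p]] <- perturbed[[p]] +
            stats::rnorm(length(rows), sd = stats::sd(perturbed[[p]]))
        }
        pr <- stats::predict(model, data = perturbed, predict.all = TRUE,
                             num.threads = 1)$predictions[, t]
        deltas[t, r] <- mean((pr - y[rows])^2) - err1[t]
      }
    }
    IS[p] <- mean(deltas, na.rm = TRUE)
  }
  pos <- pmax(IS, 0)
  rel <- if (sum(pos) > 0) pos / sum(pos) else rep(0, length(IS))
  data.frame(predictor = preds, IS = as.numeric(IS),
             relative = as.numeric(rel), row.names = NULL)
}

#' Regression evaluation metrics: R2, RMSE, RPD
#'
#' `R2 = 1 - SS_res / SS_tot`, `RMSE = sqrt(SS_res / n)`, and the ratio of
#' performance to deviation `RPD = sqrt(SS_tot) / sqrt(SS_res)` (the SD of
#' the observations over the RMSE of the predictions, up to the common
#' 1/n). The two are tied by `RPD = 1 / sqrt(1 - R2)` for `R2 < 1`.
#' Performance is rated excellent when `RPD >= 2`, fair when
#' `1.4 <= RPD < 2`, low when `RPD < 1.4`. A perfect fit reports
#' `RPD = Inf`, category excellent.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yhat predicted values.
#' @return list with `r2`, `rmse`, `rpd`, `category`, `n`.
#' @export
fit_metrics <- function(y, yhat) {
  n <- length(y)
  if (n < 2L || length(yhat) != n)
    stop("need matched y / yhat of length >= 2", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("`y` must not be constant", call. = FALSE)
  ss_res <- sum((yhat - y)^2)
  r2 <- 1 - ss_res / ss_tot
  rmse <- sqrt(ss_res / n)
  rpd_val <- if (ss_res == 0) Inf else sqrt(ss_tot / ss_res)
  category <- if (rpd_val >= 2) "excellent"
              else if (rpd_val >= 1.4) "fair" else "low"
  list(r2 = r2, rmse = rmse, rpd = rpd_val, category = category, n = n)
}

#' @rdname fit_metrics
#' @export
rpd <- function(y, yhat) fit_metrics(y, yhat)$rpd
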