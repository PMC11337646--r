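#' Stratified train/test split
#'
#' Disjoint, exhaustive split with the training fraction honored within
#' each stratum to within one row, so every experiment is represented in
#' both sets.
#'
#' @param data Data.frame.
#' @param train_frac Training fraction (default 0.8).
#' @param strata Column name or vector of stratum labels (e.g. experiment);
#'   `NULL` for unstratified.
#' @param seed Integer seed.
#' @return List `train`, `test` (data.frames), `train_idx`.
#' @export
split_train_test <- function(data, train_frac = 0.8, strata = NULL, seed = 1) {
  n <- nrow(data)
  s <- if (is.character(strata) && length(strata) == 1) data[[strata]] else strata
  if (!is.null(s)) {
    tab <- table(s)
    if (any(tab < 2)) {
      stop("stratum with a single row cannot be split: ",
           paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
    }
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(s)) s <- rep(1, n)
  idx <- unlist(lapply(split(seq_len(n), s), function(ii) {
    k <- min(length(ii) - 1, max(1, round(length(ii) * train_frac)))
    sample(ii, k)
  }), use.names = FALSE)
  idx <- sort(idx)
  list(train = data[idx, , drop = FALSE], test = data[-idx, , drop = FALSE],
       train_idx = idx)
}

#' Prediction accuracy metrics
#'
#' Coefficient of determination, root mean squared error, and relative
#' RMSE of predicted vs observed biomass:
#' \deqn{R^2 = 1 - \sum(O_i - P_i)^2 / \sum(O_i - \bar O)^2,\quad
#'       RMSE = \sqrt{\tfrac1n \sum(P_i - O_i)^2},\quad
#'       rRMSE = RMSE / \bar O.}
#' `as_printed = TRUE` computes the audit variants without the `1 -` and
#' the `1/n` (useful only for tracing legacy outputs; not the standard
#' definitions).
#'
#' @param obs,pred Observed and predicted values (g/m^2), equal length >= 2.
#' @param as_printed Audit flag (default `FALSE`).
#' @return Named vector `r2`, `rmse`, `rrmse`.
#' @export
evaluate_metrics <- function(obs, pred, as_printed = FALSE) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("var(obs) = 0: R2 undefined", call. = FALSE)
  if (mean(obs) == 0) stop("mean(obs) = 0: rRMSE undefined", call. = FALSE)
  if (as_printed) {
    rmse <- sqrt(ss_res)
    r2 <- ss_res / ss_tot
  } else {
    rmse <- sqrt(ss_res / length(obs))
    r2 <- 1 - ss_res / ss_tot
  }
  c(r2 = r2, rmse = rmse, rrmse = sqrt(ss_res / length(obs)) / mean(obs))
}

#' Model configuration for one learner family
#'
#' Learners and hyperparameter ranges follow the study protocol: PLSR
#' (components 1..p), random forest (mtry 1..p, min node size 5, variance
#' split), polynomial-kernel SVM (degree 1-2, C 100-1000, scale 1e-4 to
#' 1e-2), and gradient-boosted trees (rounds 20-40, depth 9-10, eta
#' 0.1-0.3, gamma 0.7-0.9, column subsample 0.7-1), all tuned by repeated
#' k-fold cross-validation (10 folds x 10 repeats by default). Grid
#' resolution within the continuous ranges is configurable; the defaults
#' keep 2-3 values per boosted-tree hyperparameter so that a full 10 x 10
#' repeated-CV grid search stays tractable at desk scale.
#'
#' @param learner One of `"plsr"`, `"rf"`, `"svm_poly"`, `"xgboost"`.
#' @param grid Optional data.frame of hyperparameter combinations
#'   overriding the default grid.
#' @param cv_folds,cv_repeats Cross-validation shape (defaults 10 and 10).
#' @param seed Integer seed; fold assignments are derived from
#'   `(seed, repeat index)`.
#' @param num_trees Random-forest tree count (default 300).
#' @return List of class `model_config`.
#' @export
model_config <- function(learner = c("plsr", "rf", "svm_poly", "xgboost"),
                         grid = NULL, cv_folds = 10, cv_repeats = 10,
                         seed = 1, num_trees = 300) {
  learner <- match.arg(learner)
  stopifnot(cv_folds >= 2, cv_repeats >= 1)
  structure(list(learner = learner, grid = grid, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, seed = seed, num_trees = num_trees),
            class = "model_config")
}

.default_grid <- function(learner, p) {
  switch(learner,
    plsr = data.frame(ncomp = seq_len(p)),
    rf = data.frame(mtry = seq_len(p), min_node_size = 5),
    svm_poly = expand.grid(degree = 1:2,
                           C = c(100, 550, 1000),
                           scale = c(1e-4, 1e-3, 1e-2),
                           KEEP.OUT.ATTRS = FALSE),
    xgboost = expand.grid(nrounds = c(20, 30, 40), max_depth = c(9, 10),
                          eta = c(0.1, 0.2, 0.3), gamma = c(0.7, 0.9),
                          colsample_bytree = c(0.7, 1),
                          KEEP.OUT.ATTRS = FALSE)
  )
}

# fit one learner at one hyperparameter setting; returns a predict closure
.fit_learner <- function(learner, X, y, hp, config) {
  switch(learner,
    plsr = {
      fit <- fit_plsr(X, y, ncomp = hp$ncomp)
      function(newX) predict(fit, newX, ncomp = hp$ncomp)
    },
    rf = {
      fit <- ranger::ranger(
        x = as.data.frame(X), y = y,
        mtry = min(hp$mtry, ncol(X)), min.node.size = hp$min_node_size,
        splitrule = "variance", num.trees = config$num_trees,
        num.threads = 1, seed = .derive_seed(config$seed, 77)
      )
      function(newX) stats::predict(fit, data = as.data.frame(newX))$predictions
    },
    svm_poly = {
      fit <- kernlab::ksvm(
        x = as.matrix(X), y = y, type = "eps-svr",
        kernel = "polydot",
        kpar = list(degree = hp$degree, scale = hp$scale, offset = 1),
        C = hp$C, scaled = TRUE
      )
      function(newX) as.numeric(kernlab::predict(fit, as.matrix(newX)))
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
      fit <- xgboost::xgb.train(
        params = list(max_depth = hp$max_depth, eta = hp$eta,
                      gamma = hp$gamma, colsample_bytree = hp$colsample_bytree,
                      objective = "reg:squarederror", nthread = 1,
                      seed = .derive_seed(config$seed, 78)),
        data = dtrain, nrounds = hp$nrounds, verbose = 0
      )
      function(newX) stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(newX)))
    }
  )
}

#' Train one learner with grid search under repeated k-fold CV
#'
#' For every hyperparameter combination in the grid, the training data are
#' cross-validated with `cv_folds` folds repeated `cv_repeats` times (fold
#' assignment reseeded per repeat from the config seed); the winning
#' combination minimizes the mean RMSE over the fold x repeat cells. The
#' winner is refit on the full training set; metrics on the held-out test
#' set are reported alongside the CV means (the mean of the individual
#' fold x repeat performances). Out-of-fold predictions of the winner (from
#' the first CV repeat) are retained for downstream repeatability analysis.
#'
#' @param train,test Data.frames containing `features` columns and the
#'   `response` column.
#' @param features Character vector of predictor column names.
#' @param response Response column name (default `"dw_agb"`).
#' @param config A [model_config()].
#' @return Object of class `fit_result`: `learner`, `best_hp`, `cv_metrics`
#'   (mean over 100 fold x repeat cells), `cv_cells` (per-cell metrics),
#'   `test_metrics`, `predictions` (test obs/pred), `oof_predictions`
#'   (training rows, out-of-fold), `model` (refit predict closure).
#' @export
train_model <- function(train, test, features, response = "dw_agb", config) {
  stopifnot(inherits(config, "model_config"))
  X <- as.matrix(train[, features, drop = FALSE])
  y <- train[[response]]
  if (stats::var(y) == 0) stop("degenerate response: zero variance", call. = FALSE)
  p <- length(features)
  grid <- if (is.null(config$grid)) .default_grid(config$learner, p) else config$grid
  n <- nrow(X)
  folds <- min(config$cv_folds, n)
  # fold assignment per repeat, derived deterministically from (seed, repeat)
  fold_ids <- lapply(seq_len(config$cv_repeats), function(rep_i) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(.derive_seed(config$seed, rep_i))
    sample(rep(seq_len(folds), length.out = n))
  })
  cell_rmse <- matrix(NA_real_, nrow(grid), folds * config$cv_repeats)
  oof <- matrix(NA_real_, nrow(grid), n)
  for (g in seq_len(nrow(grid))) {
    hp <- grid[g, , drop = FALSE]
    cell <- 0
    for (rep_i in seq_len(config$cv_repeats)) {
      fid <- fold_ids[[rep_i]]
      for (f in seq_len(folds)) {
        cell <- cell + 1
        tr <- fid != f
        if (stats::var(y[tr]) == 0) next
        mdl <- .fit_learner(config$learner, X[tr, , drop = FALSE], y[tr],
                            hp, config)
        pr <- mdl(X[!tr, , drop = FALSE])
        cell_rmse[g, cell] <- sqrt(mean((pr - y[!tr])^2))
        if (rep_i == 1) oof[g, !tr] <- pr
      }
    }
  }
  mean_rmse <- rowMeans(cell_rmse, na.rm = TRUE)
  best <- which.min(mean_rmse)
  best_hp <- grid[best, , drop = FALSE]
  model <- .fit_learner(config$learner, X, y, best_hp, config)
  pred_test <- model(as.matrix(test[, features, drop = FALSE]))
  obs_test <- test[[response]]
  structure(list(
    learner = config$learner, best_hp = best_hp,
    cv_metrics = c(rmse = mean_rmse[best]),
    cv_cells = cell_rmse[best, ],
    test_metrics = evaluate_metrics(obs_test, pred_test),
    predictions = data.frame(obs = obs_test, pred = pred_test),
    oof_predictions = data.frame(obs = y, pred = oof[best, ]),
    features = features, model = model
  ), class = "fit_result")
}

#' Compare a general model with level-specific models
#'
#' For an axis (`stage` or `experiment`), trains one general model on all
#' training rows and one specific model per axis level on that level's
#' training rows only, then compares their test RMSEs on each level's test
#' rows. Levels with fewer than `min_rows` rows are skipped with a warning.
#'
#' @param data Data.frame with the feature columns, the response, the axis
#'   column, and an `experiment_id` column used for stratifying the split.
#' @param axis Column name: `"stage"` or `"experiment_id"`.
#' @param features Predictor column names.
#' @param response Response column name.
#' @param config A [model_config()].
#' @param min_rows Minimum rows per level (default 10).
#' @param seed Split seed.
#' @return Data.frame, one row per level: `level`, `n_test`,
#'   `rmse_general`, `rmse_specific`, `rmse_diff`
#'   (specific minus general; negative favors the specific model).
#' @export
compare_general_specific <- function(data, axis, features,
                                     response = "dw_agb", config,
                                     min_rows = 10, seed = 1) {
  lv <- unique(as.character(data[[axis]]))
  strata <- if ("experiment_id" %in% names(data)) "experiment_id" else NULL
  sp <- split_train_test(data, 0.8, strata = strata, seed = seed)
  gen <- train_model(sp$train, sp$test, features, response, config)
  rows <- list()
  for (l in lv) {
    tr_l <- sp$train[as.character(sp$train[[axis]]) == l, , drop = FALSE]
    te_l <- sp$test[as.character(sp$test[[axis]]) == l, , drop = FALSE]
    if (nrow(tr_l) + nrow(te_l) < min_rows || nrow(te_l) < 2) {
      warning("level '", l, "' has too few rows; skipped")
      next
    }
    spec <- train_model(tr_l, te_l, features, response, config)
    pr_gen <- gen$model(as.matrix(te_l[, features, drop = FALSE]))
    rmse_gen <- sqrt(mean((pr_gen - te_l[[response]])^2))
    rows[[l]] <- data.frame(level = l, n_test = nrow(te_l),
                            rmse_general = rmse_gen,
                            rmse_specific = spec$test_metrics[["rmse"]],
                            rmse_diff = spec$test_metrics[["rmse"]] - rmse_gen)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
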