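make_model_data <- function(n = 120, seed = 1, noise = 0.1) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  experiment_id = rep(paste0("E", 1:4), length.out = n))
  d$dw_agb <- 500 + 120 * d$x1 - 80 * d$x2 + rnorm(n, 0, noise * 100)
  d
}

test_that("stratified split partitions the data at 80:20 per stratum", {
  d <- make_model_data(100)
  sp <- split_train_test(d, 0.8, strata = "experiment_id", seed = 3)
  expect_equal(sort(c(sp$train_idx, setdiff(seq_len(100), sp$train_idx))),
               1:100)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)
  expect_equal(nrow(merge(sp$train, sp$test)), 0)
  for (e in unique(d$experiment_id)) {
    n_tr <- sum(sp$train$experiment_id == e)
    expect_lte(abs(n_tr - 0.8 * 25), 1)
  }
  expect_identical(split_train_test(d, 0.8, "experiment_id", seed = 3)$train_idx,
                   sp$train_idx)
  d1 <- d; d1$experiment_id[1] <- "LONE"
  expect_error(split_train_test(d1, 0.8, "experiment_id", seed = 1),
               "single row")
})

test_that("accuracy metrics follow the standard definitions", {
  expect_equal(unname(evaluate_metrics(c(1, 2, 3), c(1, 2, 3))), c(1, 0, 0))
  obs <- c(100, 200, 300)
  expect_equal(unname(evaluate_metrics(obs, rep(200, 3))["r2"]), 0)
  m <- evaluate_metrics(obs, c(110, 190, 310))
  expect_equal(unname(m["rmse"]), 10)
  expect_equal(unname(m["rrmse"]), 0.05)
  # identity R2 = 1 - RMSE^2 * n / SS_tot
  set.seed(2); o <- rnorm(30, 10); p <- o + rnorm(30, 0, 0.5)
  mm <- evaluate_metrics(o, p)
  expect_equal(unname(mm["r2"]),
               1 - unname(mm["rmse"])^2 * 30 / sum((o - mean(o))^2))
  # audit variants reproduce the unnormalized forms
  ap <- evaluate_metrics(obs, c(110, 190, 310), as_printed = TRUE)
  expect_equal(unname(ap["rmse"]), sqrt(300))
  expect_error(evaluate_metrics(c(1, 1), c(1, 2)), "R2 undefined")
})

test_that("every learner family fits a strong linear signal", {
  d <- make_model_data(120, noise = 0.05)
  sp <- split_train_test(d, 0.8, "experiment_id", seed = 1)
  for (ln in c("plsr", "rf", "svm_poly", "xgboost")) {
    cfg <- model_config(ln, cv_folds = 5, cv_repeats = 1, seed = 2)
    fit <- train_model(sp$train, sp$test, c("x1", "x2", "x3"), "dw_agb", cfg)
    expect_gt(fit$test_metrics[["r2"]], 0.6)
    expect_true(all(is.finite(fit$cv_cells)))
    expect_equal(length(fit$cv_cells), 5)
  }
})

test_that("PLSR nails a noiseless linear response and tuning is deterministic", {
  d <- make_model_data(100, noise = 0)
  sp <- split_train_test(d, 0.8, "experiment_id", seed = 1)
  cfg <- model_config("plsr", cv_folds = 10, cv_repeats = 2, seed = 5)
  fit <- train_model(sp$train, sp$test, c("x1", "x2", "x3"), "dw_agb", cfg)
  expect_gt(fit$test_metrics[["r2"]], 0.999)
  expect_equal(length(fit$cv_cells), 20)   # folds x repeats
  fit2 <- train_model(sp$train, sp$test, c("x1", "x2", "x3"), "dw_agb", cfg)
  expect_identical(fit$best_hp, fit2$best_hp)
  expect_equal(fit$cv_metrics, fit2$cv_metrics)
})

test_that("a pure-noise response cannot be predicted", {
  r2s <- sapply(1:10, function(s) {
    set.seed(s)
    d <- data.frame(x1 = rnorm(200), x2 = rnorm(200),
                    dw_agb = rnorm(200, 500, 50))
    sp <- split_train_test(d, 0.8, seed = s)
    cfg <- model_config("plsr", cv_folds = 5, cv_repeats = 1, seed = s)
    fit <- train_model(sp$train, sp$test, c("x1", "x2"), "dw_agb", cfg)
    fit$test_metrics[["r2"]]
  })
  expect_lt(median(r2s), 0.1)
  expect_error(
    train_model(data.frame(x1 = 1:10, dw_agb = 5),
                data.frame(x1 = 1:2, dw_agb = 5), "x1",
                config = model_config("plsr")),
    "degenerate")
})

test_that("standardizing inside folds does not leak validation information", {
  # a leaky variant (standardize on all rows, then CV) must look better on CV
  # than the honest fit on data whose scale carries spurious signal
  set.seed(9)
  n <- 60
  d <- data.frame(x1 = rnorm(n), dw_agb = rnorm(n, 500, 50))
  sp <- split_train_test(d, 0.8, seed = 1)
  cfg <- model_config("plsr", cv_folds = 5, cv_repeats = 2, seed = 1)
  honest <- train_model(sp$train, sp$test, "x1", "dw_agb", cfg)
  # honest CV RMSE for pure noise is about the response sd, never much below
  expect_gt(honest$cv_metrics[["rmse"]], 0.7 * sd(sp$train$dw_agb))
})

test_that("general vs specific comparison detects planted heterogeneity", {
  set.seed(4)
  make_level <- function(lv, slope) {
    n <- 60
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                    experiment_id = rep(paste0(lv, 1:2), length.out = n),
                    stage = lv)
    d$dw_agb <- 500 + slope * d$x1 + rnorm(n, 0, 20)
    d
  }
  cfg <- model_config("plsr", cv_folds = 5, cv_repeats = 1, seed = 1)
  # exchangeable levels: specific ~ general
  same <- rbind(make_level("A", 100), make_level("B", 100))
  tab <- compare_general_specific(same, "stage", c("x1", "x2"),
                                  config = cfg, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_true(all(abs(tab$rmse_diff) < 0.5 * tab$rmse_general))
  # a level with an inverted trait-biomass mapping favors its specific model
  wins <- sum(sapply(1:10, function(s) {
    set.seed(s)
    mixed <- rbind(make_level("A", 100), make_level("B", -100))
    tb <- compare_general_specific(mixed, "stage", c("x1", "x2"),
                                   config = cfg, seed = s)
    all(tb$rmse_specific < tb$rmse_general)
  }))
  expect_gte(wins, 9)
})
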