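test_that("regression metrics follow their definitions", {
  expect_equal(metric_mae(c(1, 2), c(2, 2)), 0.5)
  expect_equal(metric_mae(1:5, 1:5), 0)
  expect_equal(metric_mae(c(0, 0, 0), c(1, -1, 1)), 1)
  expect_equal(metric_rmse(c(1, 2), c(2, 2)), sqrt(0.5))
  expect_equal(metric_rmse(1:5, 1:5), 0)
  expect_error(metric_mae(1:3, 1:2), "equal")
  # MAE/STD: constant-mean predictor scores 1 on a symmetric target
  y <- c(0, 2)
  expect_equal(metric_mae_std(y, rep(mean(y), 2)), 1)
  expect_equal(metric_mae_std(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(metric_mae_std(c(0, 0, 3, 3), c(0, 0, 0, 0)), 1)  # 1.5 / 1.5
  expect_error(metric_mae_std(c(2, 2), c(1, 2)), "zero variance")
})

test_that("MAE never exceeds RMSE", {
  set.seed(13)
  for (k in 1:300) {
    n <- sample(2:50, 1)
    y <- rnorm(n, sd = runif(1, 0.1, 10))
    yhat <- y + rnorm(n, sd = runif(1, 0.1, 10))
    expect_lte(metric_mae(y, yhat), metric_rmse(y, yhat) + 1e-12)
  }
})

test_that("binary cross-entropy and accuracy behave at the reference points", {
  expect_equal(metric_bce(1, 0.5), log(2))
  expect_lt(metric_bce(1, 1 - 1e-12), 1e-11)
  expect_equal(metric_bce(c(1, 0), c(0.9, 0.1)), -log(0.9))
  expect_error(metric_bce(1, 1.2), "\\[0, 1\\]")
  expect_error(metric_bce(0.5, 0.5), "0/1")
  expect_equal(metric_accuracy(list(TP = 3, TN = 2, FP = 1, FN = 2)), 0.625)
  expect_equal(metric_accuracy(list(TP = 9, TN = 4, FP = 0, FN = 0)), 1)
  expect_equal(metric_accuracy(list(TP = 0, TN = 0, FP = 3, FN = 1)), 0)
  expect_error(metric_accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("importance scaling is exact min-max with a degenerate rule", {
  raw <- c(a = 0.2, b = 0.5, c = 0.8)
  expect_equal(scale_importance(raw), c(a = 0, b = 0.5, c = 1))
  expect_equal(suppressMessages(scale_importance(c(x = 7, y = 7, z = 7))),
               c(x = 0, y = 0, z = 0))
  set.seed(14)
  r <- runif(10); names(r) <- letters[1:10]
  s <- scale_importance(r)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  expect_error(scale_importance(numeric()), "empty")
})

test_that("key features require strictly exceeding the threshold", {
  expect_identical(key_features(c(a = 1, b = 0.9, c = 0.3)), c("a", "b"))
  expect_identical(key_features(c(a = 0.85)), character(0))
  expect_identical(key_features(c(a = 0, b = 0)), character(0))
  # sorted by descending importance
  expect_identical(key_features(c(lo = 0.9, hi = 1.0)), c("hi", "lo"))
})

test_that("train_eval learns a planted regression signal", {
  spec <- generator_spec(n_rows = 300, n_copies = 0, n_constant = 0,
                         n_local = 0, seed = 42)
  ft <- generate_feature_table(spec)
  y <- generate_regression_targets(ft, c(TPSA = 3, BDE = -2), seed = 42)
  ev <- train_eval(ft, y, task_spec("toy", "regression", seed = 42),
                   params = xgb_params(nrounds = 150))
  expect_lt(ev$metrics$test$MAE_STD, 0.5)
  expect_lte(ev$metrics$test$MAE, ev$metrics$test$RMSE)
  top <- names(sort(ev$raw_importance, decreasing = TRUE))[1:3]
  expect_true(all(c("TPSA", "BDE") %in% top))
  expect_equal(min(ev$scaled_importance), 0)
  expect_equal(max(ev$scaled_importance), 1)
  # determinism at fixed seed
  ev2 <- train_eval(ft, y, task_spec("toy", "regression", seed = 42),
                    params = xgb_params(nrounds = 150))
  expect_equal(ev$metrics$test$MAE, ev2$metrics$test$MAE)
})

test_that("train_eval classification reports a consistent confusion matrix", {
  spec <- generator_spec(n_rows = 400, n_copies = 0, n_constant = 0,
                         n_local = 0, seed = 15)
  ft <- generate_feature_table(spec)
  cl <- generate_classification_targets(ft, c(TPSA = 3, BDE = -2),
                                        separation = 2, seed = 15,
                                        positive_rate = 0.5)
  ev <- train_eval(ft, cl$labels,
                   task_spec("toycls", "classification", seed = 42),
                   params = xgb_params(nrounds = 150))
  expect_gt(ev$metrics$test$accuracy, 0.9)
  cf <- ev$confusion$test
  expect_equal(metric_accuracy(cf),
               mean(ev$predictions$test$y == ev$predictions$test$pred))
  expect_equal(cf$TP + cf$FP + cf$TN + cf$FN, nrow(ev$predictions$test))
  # the stratified split keeps both classes in both partitions
  expect_true(all(c(0, 1) %in% ev$predictions$train$y))
  expect_true(all(c(0, 1) %in% ev$predictions$test$y))
})

test_that("train_eval refuses undersized tables and handles missing rows", {
  ft <- tiny_feature_table(n = 8)
  expect_error(train_eval(ft, rnorm(8), task_spec("t", "regression")),
               "fewer than 10")
  spec <- generator_spec(n_rows = 60, n_copies = 0, n_constant = 0,
                         n_local = 0, seed = 16)
  big <- generate_feature_table(spec)
  y <- generate_regression_targets(big, c(TPSA = 1), seed = 16)
  big$values[1:5, "TPSA"] <- NA
  expect_message(
    ev <- train_eval(big, y, task_spec("t", "regression", seed = 1),
                     params = xgb_params(nrounds = 20)),
    "5 row")
  expect_equal(nrow(ev$predictions$train) + nrow(ev$predictions$test), 55L)
})

test_that("the teac transform feeds regression targets", {
  spec <- generator_spec(n_rows = 60, n_copies = 0, n_constant = 0,
                         n_local = 0, seed = 17)
  ft <- generate_feature_table(spec)
  ic50 <- exp(rnorm(60, 2, 0.3))
  ev <- train_eval(ft, ic50,
                   task_spec("abts", "regression", transform = "teac",
                             ic50_trolox = 10, seed = 1),
                   params = xgb_params(nrounds = 20))
  expect_true(is.finite(ev$metrics$test$MAE))
  got <- sort(c(ev$predictions$train$y, ev$predictions$test$y))
  expect_equal(got, sort(teac(10, ic50)))
})
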