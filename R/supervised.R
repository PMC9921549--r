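#' Mean absolute error
#' @param y,yhat Numeric vectors of equal nonzero length.
#' @return `mean(|y - yhat|)`.
#' @export
metric_mae <- function(y, yhat) {
  check_lengths(y, yhat)
  mean(abs(y - yhat))
}

#' Root-mean-square error
#' @param y,yhat Numeric vectors of equal nonzero length.
#' @return `sqrt(mean((y - yhat)^2))`; always >= [metric_mae()] on the same
#'   input (power-mean inequality).
#' @export
metric_rmse <- function(y, yhat) {
  check_lengths(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' MAE scaled by the target spread
#'
#' MAE divided by the population (denominator n) standard deviation of the
#' observed targets, making errors comparable across assays with different
#' target scales. A best-constant predictor scores about 1.
#'
#' @param y,yhat Numeric vectors of equal nonzero length; `sd(y)` must be
#'   positive.
#' @return `metric_mae(y, yhat) / sd_pop(y)`.
#' @export
metric_mae_std <- function(y, yhat) {
  check_lengths(y, yhat)
  s <- sd_pop(y)
  if (s <= 0) stop("targets have zero variance", call. = FALSE)
  metric_mae(y, yhat) / s
}

#' Binary cross-entropy
#'
#' Mean of `-[y*ln(p) + (1-y)*ln(1-p)]` with natural logarithm;
#' probabilities are clipped to `[1e-15, 1 - 1e-15]` first.
#'
#' @param y Vector of 0/1 labels.
#' @param p Predicted probabilities of class 1, in `[0, 1]`.
#' @return Mean binary cross-entropy in nats.
#' @examples
#' metric_bce(1, 0.5)  # log(2)
#' @export
metric_bce <- function(y, p) {
  check_lengths(y, p)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Accuracy from a confusion matrix
#' @param confusion List or named vector with `TP`, `FP`, `TN`, `FN`.
#' @return `(TP + TN) / (TP + TN + FP + FN)`.
#' @export
metric_accuracy <- function(confusion) {
  confusion <- as.list(confusion)
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(confusion)))
    stop("confusion needs TP, FP, TN, FN", call. = FALSE)
  tot <- confusion$TP + confusion$TN + confusion$FP + confusion$FN
  if (tot <= 0) stop("empty confusion matrix", call. = FALSE)
  (confusion$TP + confusion$TN) / tot
}

#' Min-max scale feature importances
#'
#' Linear rescaling so the most important feature maps to exactly 1 and the
#' least important to exactly 0. With all raw values equal the scaling is
#' degenerate; everything maps to 0 (reported with a message).
#'
#' @param raw Named numeric vector of non-negative raw importances, length
#'   >= 1.
#' @return Named numeric vector in `[0, 1]`.
#' @export
scale_importance <- function(raw) {
  if (!length(raw)) stop("empty importance vector", call. = FALSE)
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    message("all raw importances equal; scaled importances set to 0")
    out <- rep(0, length(raw)); names(out) <- names(raw)
    return(out)
  }
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Key features above the scaled-importance threshold
#'
#' @param scaled Named numeric vector of scaled importances in `[0, 1]`.
#' @param threshold Strict cut-off in `[0, 1]`; default 0.85. A feature at
#'   exactly the threshold is not a key feature.
#' @return Character vector of feature names with `scaled > threshold`,
#'   sorted by descending importance.
#' @export
key_features <- function(scaled, threshold = 0.85) {
  stopifnot(threshold >= 0, threshold <= 1)
  sel <- scaled[scaled > threshold]
  names(sel)[order(-sel)]
}

#' Task specification for supervised evaluation
#'
#' @param name Dataset/assay name.
#' @param task_type `"regression"` or `"classification"`.
#' @param transform Target transform: `"none"`, `"teac"` (targets are IC50s
#'   converted with [teac()] against `ic50_trolox`), or `"dpph_binarize"`
#'   (IC50s binarized with [binarize_dpph()]; classification only).
#' @param train_fraction Fraction of rows used for training; default 0.8.
#'   The split is stratified by class for classification.
#' @param seed Split (and model) seed; default 42.
#' @param ic50_trolox Trolox IC50 for the `"teac"` transform.
#' @param dpph_threshold IC50 cut-off for `"dpph_binarize"`; default 300.
#' @return A list of class `task_spec`.
#' @export
task_spec <- function(name, task_type = c("regression", "classification"),
                      transform = c("none", "teac", "dpph_binarize"),
                      train_fraction = 0.8, seed = 42,
                      ic50_trolox = NULL, dpph_threshold = 300) {
  task_type <- match.arg(task_type)
  transform <- match.arg(transform)
  if (transform == "dpph_binarize" && task_type != "classification")
    stop("dpph_binarize implies a classification task", call. = FALSE)
  if (transform == "teac" && is.null(ic50_trolox))
    stop("the teac transform needs `ic50_trolox`", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(name = name, task_type = task_type, transform = transform,
                 train_fraction = train_fraction, seed = seed,
                 ic50_trolox = ic50_trolox, dpph_threshold = dpph_threshold),
            class = "task_spec")
}

#' Default gradient-boosting parameters
#'
#' Fixed, documented defaults (no automated hyperparameter search): 300
#' boosting rounds, learning rate 0.1, depth-4 trees, single thread for
#' determinism. Regression uses an MAE-oriented loss
#' (`reg:absoluteerror`), classification binary cross-entropy
#' (`binary:logistic`).
#'
#' @param nrounds,eta,max_depth,subsample,colsample_bytree,min_child_weight
#'   Usual gradient-boosting controls.
#' @return A list of class `xgb_params`.
#' @export
xgb_params <- function(nrounds = 300, eta = 0.1, max_depth = 4,
                       subsample = 1, colsample_bytree = 1,
                       min_child_weight = 1) {
  structure(list(nrounds = nrounds, eta = eta, max_depth = max_depth,
                 subsample = subsample, colsample_bytree = colsample_bytree,
                 min_child_weight = min_child_weight),
            class = "xgb_params")
}

confusion_counts <- function(y, pred) {
  list(TP = sum(y == 1 & pred == 1), FP = sum(y == 0 & pred == 1),
       TN = sum(y == 0 & pred == 0), FN = sum(y == 1 & pred == 0))
}

#' Train and evaluate a gradient-boosted model on the common features
#'
#' Fits a gradient-boosted decision-tree ensemble (XGBoost) on a
#' train/test split and reports the assay-comparison metrics: MAE, RMSE and
#' MAE/STD for regression; binary cross-entropy, accuracy and the confusion
#' matrix for classification (0.5 probability cut). Tree-gain importances
#' are returned raw, min-max scaled ([scale_importance()]), and thresholded
#' into key features ([key_features()]). Rows with missing feature values
#' are dropped here, at model time (count reported).
#'
#' @param table A `feature_table` restricted to the selected features.
#' @param targets Numeric targets (regression), or 0/1 / factor labels
#'   (classification); for the `"teac"` and `"dpph_binarize"` transforms,
#'   raw IC50 values in micromolar.
#' @param spec A [task_spec()].
#' @param params An [xgb_params()].
#' @param key_threshold Scaled-importance cut-off for key features,
#'   default 0.85.
#' @return An object of class `model_evaluation` with `metrics` (`$train`,
#'   `$test`), `confusion` (classification), `raw_importance`,
#'   `scaled_importance`, `key_features`, `predictions` and `spec`.
#' @export
train_eval <- function(table, targets, spec, params = xgb_params(),
                       key_threshold = 0.85) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "task_spec"),
            inherits(params, "xgb_params"))
  x <- table$values
  if (length(targets) != nrow(x))
    stop("targets must match the number of rows", call. = FALSE)

  y <- targets
  if (spec$transform == "teac") y <- teac(spec$ic50_trolox, as.numeric(y))
  if (spec$transform == "dpph_binarize")
    y <- binarize_dpph(as.numeric(y), spec$dpph_threshold)
  if (spec$task_type == "classification") {
    if (is.factor(y)) {
      pos <- if ("positive" %in% levels(y)) "positive" else levels(y)[2L]
      y <- as.integer(y == pos)
    }
    if (is.logical(y)) y <- as.integer(y)
    if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  } else {
    y <- as.numeric(y)
  }

  usable <- stats::complete.cases(x) & !is.na(y)
  n_dropped <- sum(!usable)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing values dropped at model time")
  x <- x[usable, , drop = FALSE]
  y <- y[usable]
  if (nrow(x) < 10L)
    stop("fewer than 10 usable rows; refusing to fit", call. = FALSE)

  set.seed(spec$seed)
  n <- nrow(x)
  if (spec$task_type == "classification") {
    idx_train <- integer()
    for (cls in unique(y)) {
      rows <- which(y == cls)
      k <- max(1L, round(spec$train_fraction * length(rows)))
      idx_train <- c(idx_train, sample(rows, k))
    }
    idx_train <- sort(idx_train)
  } else {
    idx_train <- sort(sample.int(n, max(2L, round(spec$train_fraction * n))))
  }
  idx_test <- setdiff(seq_len(n), idx_train)
  if (!length(idx_test))
    stop("train fraction leaves no test rows", call. = FALSE)

  objective <- if (spec$task_type == "regression") "reg:absoluteerror"
    else "binary:logistic"
  dtrain <- xgboost::xgb.DMatrix(x[idx_train, , drop = FALSE],
                                 label = y[idx_train], nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = objective, eta = params$eta,
                  max_depth = params$max_depth, subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree,
                  min_child_weight = params$min_child_weight,
                  nthread = 1, seed = spec$seed),
    data = dtrain, nrounds = params$nrounds, verbose = 0)

  predict_on <- function(idx)
    stats::predict(booster,
                   xgboost::xgb.DMatrix(x[idx, , drop = FALSE], nthread = 1))
  eval_split <- function(idx) {
    yhat <- predict_on(idx)
    if (spec$task_type == "regression") {
      list(metrics = list(MAE = metric_mae(y[idx], yhat),
                          RMSE = metric_rmse(y[idx], yhat),
                          MAE_STD = metric_mae_std(y[idx], yhat)),
           confusion = NULL,
           predictions = data.frame(row = idx, y = y[idx], yhat = yhat))
    } else {
      pred <- as.integer(yhat >= 0.5)
      conf <- confusion_counts(y[idx], pred)
      list(metrics = list(BCE = metric_bce(y[idx], yhat),
                          accuracy = metric_accuracy(conf)),
           confusion = conf,
           predictions = data.frame(row = idx, y = y[idx], p = yhat,
                                    pred = pred))
    }
  }
  ev_train <- eval_split(idx_train)
  ev_test <- eval_split(idx_test)

  imp <- xgboost::xgb.importance(model = booster)
  raw <- rep(0, ncol(x))
  names(raw) <- colnames(x)
  if (!is.null(imp) && nrow(imp)) raw[imp$Feature] <- imp$Gain
  scaled <- scale_importance(raw)
  structure(list(metrics = list(train = ev_train$metrics,
                                test = ev_test$metrics),
                 confusion = list(train = ev_train$confusion,
                                  test = ev_test$confusion),
                 raw_importance = raw,
                 scaled_importance = scaled,
                 key_features = key_features(scaled, key_threshold),
                 predictions = list(train = ev_train$predictions,
                                    test = ev_test$predictions),
                 spec = spec, params = params, model = booster),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %s (%s)\n", x$spec$name, x$spec$task_type))
  for (split in c("train", "test")) {
    m <- x$metrics[[split]]
    cat("  ", split, ": ",
        paste(sprintf("%s=%.4f", names(m), unlist(m)), collapse = " "),
        "\n", sep = "")
  }
  cat("  key features:",
      if (length(x$key_features)) paste(x$key_features, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

check_lengths <- function(a, b) {
  if (length(a) != length(b) || !length(a))
    stop("inputs must have equal nonzero length", call. = FALSE)
  invisible(TRUE)
}

# population (denominator n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
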