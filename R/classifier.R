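chip_classes <- function() c("CHIP", "GERMLINE", "ARTIFACT")

#' Training configuration
#'
#' @param model_kind `"gbt"` (gradient-boosted trees) or `"rf"` (random
#'   forest).
#' @param data_type `"WES"`, `"WGS"` or `"WES+WGS"` -- a tag carried by the
#'   model (models are trained separately per data type and variant type).
#' @param variant_type `"SNV"` or `"INDEL"`.
#' @param train_fraction fraction of rows used for training (default 0.8).
#' @param cv_folds folds for optional hyperparameter tuning (default 5).
#' @param seed integer seed.
#' @param hyperparameters named list overriding the pinned defaults
#'   (gbt: 300 trees, depth 6, learning rate 0.1; rf: 500 trees,
#'   sqrt-features).
#' @export
train_config <- function(model_kind = c("gbt", "rf"),
                         data_type = c("WES", "WGS", "WES+WGS"),
                         variant_type = c("SNV", "INDEL"),
                         train_fraction = 0.8, cv_folds = 5L, seed = 1L,
                         hyperparameters = list()) {
  model_kind <- match.arg(model_kind)
  data_type <- match.arg(data_type)
  variant_type <- match.arg(variant_type)
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2)
  hp <- if (model_kind == "gbt")
    list(nrounds = 300L, max_depth = 6L, eta = 0.1)
  else
    list(ntree = 500L, mtry = NULL)
  hp[names(hyperparameters)] <- hyperparameters
  structure(list(model_kind = model_kind, data_type = data_type,
                 variant_type = variant_type,
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 hyperparameters = hp), class = "train_config")
}

#' Stratified train/test split
#'
#' Splits labeled feature rows into train and test sets, stratified by
#' class. Membership is decided by a per-row content hash mixed with the
#' seed, so the split is deterministic given the seed and invariant to the
#' input row order. A class with a single row goes to the training set.
#'
#' @param df data.frame with a `label` column and feature columns.
#' @param cfg a [train_config()].
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(df, cfg) {
  stopifnot(nrow(df) >= 10L, "label" %in% names(df))
  present <- unique(as.character(df$label))
  absent <- setdiff(chip_classes(), present)
  if (length(absent))
    warnf("class(es) absent from the data: %s", paste(absent, collapse = ", "))
  rowkey <- apply(df, 1L, function(r)
    fnv1a32(paste(c(cfg$seed, r), collapse = "\r")))
  train_idx <- logical(nrow(df))
  for (cl in present) {
    idx <- which(df$label == cl)
    if (length(idx) == 1L) { train_idx[idx] <- TRUE; next }
    ord <- idx[order(rowkey[idx], idx)]
    n_train <- round(cfg$train_fraction * length(idx))
    n_train <- min(max(n_train, 1L), length(idx) - 1L)
    train_idx[ord[seq_len(n_train)]] <- TRUE
  }
  list(train = df[train_idx, , drop = FALSE],
       test = df[!train_idx, , drop = FALSE])
}

feature_matrix <- function(df, feature_names) {
  miss <- setdiff(feature_names, names(df))
  if (length(miss)) stopf("missing feature column(s): %s",
                          paste(miss, collapse = ", "))
  m <- as.matrix(df[, feature_names, drop = FALSE])
  bad <- colnames(m)[apply(m, 2L, function(x) any(is.na(x) | is.nan(x)))]
  if (length(bad)) stopf("NaN/NA in feature(s): %s", paste(bad, collapse = ", "))
  storage.mode(m) <- "double"
  m
}

#' Train a three-class variant classifier
#'
#' Fits a gradient-boosted-tree (xgboost) or random-forest model
#' predicting CHIP / GERMLINE / ARTIFACT from the frozen feature schema.
#' Training is deterministic given the seed (single-threaded boosting).
#' The returned model embeds the schema hash; prediction refuses input
#' whose schema differs. Optional hyperparameter tuning runs a small
#' k-fold cross-validated grid.
#'
#' @param df data.frame with `label` and the [feature_schema()] columns.
#' @param cfg a [train_config()].
#' @param tune run the k-fold tuning grid before the final fit.
#' @return object of class `chip_model`.
#' @export
train_classifier <- function(df, cfg, tune = FALSE) {
  feats <- feature_schema(cfg$variant_type)
  X <- feature_matrix(df, feats)
  y <- factor(as.character(df$label), levels = chip_classes())
  present <- levels(droplevels(y))
  if (length(present) == 1L) {
    model <- structure(list(kind = "constant", constant_class = present,
                            classes = chip_classes(),
                            feature_names = feats,
                            schema_hash = schema_hash(feats), cfg = cfg),
                       class = "chip_model")
    return(model)
  }
  hp <- cfg$hyperparameters
  if (tune) hp <- tune_hyperparameters(X, y, cfg)
  fit <- fit_one(X, y, cfg$model_kind, hp, cfg$seed)
  structure(list(kind = cfg$model_kind, fit = fit$fit, raw = fit$raw,
                 classes = chip_classes(), feature_names = feats,
                 schema_hash = schema_hash(feats), cfg = cfg,
                 hyperparameters = hp),
            class = "chip_model")
}

fit_one <- function(X, y, kind, hp, seed) {
  if (kind == "gbt") {
    dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
    params <- list(objective = "multi:softprob", num_class = 3L,
                   max_depth = hp$max_depth, eta = hp$eta,
                   nthread = 1L, seed = seed,
                   eval_metric = "mlogloss")
    bst <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = hp$nrounds, verbose = 0)
    list(fit = bst, raw = xgboost::xgb.save.raw(bst))
  } else {
    mtry <- hp$mtry %||% max(1L, floor(sqrt(ncol(X))))
    rf <- with_seed(seed,
      randomForest::randomForest(x = X, y = droplevels(y),
                                 ntree = hp$ntree, mtry = mtry))
    list(fit = rf, raw = NULL)
  }
}

tune_hyperparameters <- function(X, y, cfg) {
  grid <- if (cfg$model_kind == "gbt")
    expand.grid(max_depth = c(4L, 6L), eta = c(0.1, 0.3))
  else
    expand.grid(mtry = unique(c(max(1L, floor(sqrt(ncol(X)) / 2)),
                                floor(sqrt(ncol(X))))))
  folds <- with_seed(cfg$seed,
                     sample(rep(seq_len(cfg$cv_folds), length.out = nrow(X))))
  best <- NULL; best_f1 <- -Inf
  for (gi in seq_len(nrow(grid))) {
    hp <- cfg$hyperparameters
    hp[names(grid)] <- as.list(grid[gi, , drop = FALSE])
    if (cfg$model_kind == "gbt") hp$nrounds <- 100L
    f1s <- vapply(seq_len(cfg$cv_folds), function(k) {
      tr <- folds != k
      fit <- fit_one(X[tr, , drop = FALSE], y[tr], cfg$model_kind, hp,
                     cfg$seed + k)
      pr <- predict_probs(fit$fit, cfg$model_kind,
                          X[!tr, , drop = FALSE])
      lab <- chip_classes()[max.col(pr, ties.method = "first")]
      cm <- confusion(lab, as.character(y[!tr]))
      macro_f1(cm)
    }, numeric(1))
    if (mean(f1s) > best_f1) { best_f1 <- mean(f1s); best <- hp }
  }
  if (cfg$model_kind == "gbt") best$nrounds <- cfg$hyperparameters$nrounds
  best
}

predict_probs <- function(fit, kind, X) {
  if (kind == "gbt") {
    p <- predict(fit, xgboost::xgb.DMatrix(X))
    if (!is.matrix(p))
      p <- matrix(p, ncol = 3L, byrow = TRUE)
    dimnames(p) <- list(NULL, chip_classes())
    p
  } else {
    p <- predict(fit, X, type = "prob")
    full <- matrix(0, nrow(X), 3L, dimnames = list(NULL, chip_classes()))
    full[, colnames(p)] <- p
    full
  }
}

#' @export
print.chip_model <- function(x, ...) {
  cat(sprintf("<chip_model> %s | %s %s | features %d | schema %s\n",
              x$kind, x$cfg$data_type %||% "", x$cfg$variant_type %||% "",
              length(x$feature_names), x$schema_hash))
  invisible(x)
}

#' Predict classes for feature rows
#'
#' Returns class probabilities and the argmax label (exact ties resolve to
#' the first class in the fixed CHIP, GERMLINE, ARTIFACT order). The input
#' schema must hash-match the training schema.
#'
#' @param object a `chip_model`.
#' @param newdata data.frame or matrix with the model's feature columns.
#' @param ... unused.
#' @return data.frame: `label`, `prob_chip`, `prob_germline`,
#'   `prob_artifact`.
#' @export
predict.chip_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  if (!all(object$feature_names %in% names(nd)) ||
      schema_hash(object$feature_names) != object$schema_hash)
    stopf("feature schema mismatch: model expects [%s]",
          paste(object$feature_names, collapse = ", "))
  X <- feature_matrix(nd, object$feature_names)
  if (object$kind == "constant") {
    p <- matrix(0, nrow(X), 3L, dimnames = list(NULL, chip_classes()))
    p[, object$constant_class] <- 1
  } else {
    p <- predict_probs(object$fit, object$kind, X)
  }
  stopifnot(all(abs(rowSums(p) - 1) < 1e-6))
  lab <- chip_classes()[max.col(p, ties.method = "first")]
  data.frame(label = lab, prob_chip = p[, "CHIP"],
             prob_germline = p[, "GERMLINE"],
             prob_artifact = p[, "ARTIFACT"], stringsAsFactors = FALSE)
}

#' Save / load a model bundle
#'
#' Single-file bundle carrying the model, schema hash, configuration and
#' seed; boosted trees are stored in xgboost's raw serialized form so the
#' bundle survives `readRDS` across sessions.
#'
#' @param model a `chip_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  if (model$kind == "gbt") model$fit <- NULL   # raw bytes carry the booster
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (model$kind == "gbt")
    model$fit <- xgboost::xgb.load.raw(model$raw)
  model
}

#' Three-class confusion matrix
#'
#' Counts of (actual, predicted) pairs over the fixed CHIP / GERMLINE /
#' ARTIFACT order; rows are actual classes.
#'
#' @param predicted,actual character vectors of class labels.
#' @return 3x3 integer matrix.
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stopf("predicted and actual labels differ in length (%d vs %d)",
          length(predicted), length(actual))
  cls <- chip_classes()
  m <- table(factor(actual, levels = cls), factor(predicted, levels = cls))
  m <- matrix(as.integer(m), 3L, 3L, dimnames = list(actual = cls,
                                                     predicted = cls))
  m
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * P * R / (P + R)`; `NaN` when both are zero.
#'
#' @param precision,recall numeric in [0, 1].
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, NaN,
         2 * precision * recall / (precision + recall))
}

#' One-vs-rest metrics from a confusion matrix
#'
#' Reduces the 3x3 matrix to TP/FP/FN/TN for the focal class and computes
#' precision, recall (sensitivity), specificity, F1 and accuracy. Undefined
#' ratios (zero denominators) come back as `NaN` with `undefined = TRUE`.
#'
#' @param cm matrix from [confusion()].
#' @param class focal class.
#' @return list of metrics plus the reduced counts.
#' @export
metrics_from_confusion <- function(cm, class = "CHIP") {
  stopifnot(sum(cm) > 0, class %in% rownames(cm))
  tp <- cm[class, class]
  fp <- sum(cm[, class]) - tp
  fn <- sum(cm[class, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  div <- function(a, b) if (b == 0) NaN else a / b
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  list(precision = precision, recall = recall,
       specificity = div(tn, tn + fp),
       f1 = f1_score(precision, recall),
       accuracy = div(tp + tn, tp + tn + fp + fn),
       tp = tp, fp = fp, fn = fn, tn = tn,
       undefined = any(is.nan(c(precision, recall))))
}

macro_f1 <- function(cm) {
  f1s <- vapply(rownames(cm), function(cl) {
    if (sum(cm[cl, ]) == 0) return(NA_real_)
    f <- metrics_from_confusion(cm, cl)$f1
    if (is.nan(f)) 0 else f
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

#' Gain-based feature importance
#'
#' Split-gain totals per feature, normalized to sum to one, in descending
#' order; features never used in a split report zero. Boosted trees use
#' xgboost's gain; random forests use the mean decrease in node impurity
#' (the forest's analogue of split gain).
#'
#' @param model a `chip_model` backed by a tree ensemble.
#' @return named numeric vector summing to 1.
#' @export
feature_gain <- function(model) {
  stopifnot(inherits(model, "chip_model"))
  if (model$kind == "constant")
    stopf("feature_gain() needs a tree-ensemble model")
  g <- setNames(numeric(length(model$feature_names)), model$feature_names)
  if (model$kind == "gbt") {
    imp <- xgboost::xgb.importance(model = model$fit)
    g[imp$Feature] <- imp$Gain
  } else {
    imp <- randomForest::importance(model$fit)[, "MeanDecreaseGini"]
    g[names(imp)] <- imp
  }
  if (sum(g) > 0) g <- g / sum(g)
  sort(g, decreasing = TRUE)
}
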