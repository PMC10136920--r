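#' Train a per-window apnea classifier
#'
#' Fits the window classifier on an imputed feature matrix. The random forest
#' is the production model; SVM (radial), k-nearest-neighbour and gradient
#' boosted trees are provided as comparators. Training is deterministic under
#' a fixed seed and the returned object carries everything needed to predict:
#' the fitted model, the feature order, the imputation medians and an
#' optional feature-selection mask.
#'
#' @param features Numeric matrix (rows = windows) or a `feature_matrix`
#'   from [assemble_features()] (its labels/medians are then used).
#' @param labels Binary 0/1 window labels (ignored when `features` is a
#'   `feature_matrix` that carries labels).
#' @param model_kind One of `"rf"`, `"svm"`, `"knn"`, `"xgb"`.
#' @param seed RNG seed.
#' @param ntree Random-forest size (default 500).
#' @param knn_k Neighbours for `"knn"` (default 5).
#' @param nrounds Boosting rounds for `"xgb"` (default 60).
#' @param selection Optional logical column mask from [select_features()].
#' @return An `apnea_model`.
#' @export
train_model <- function(features, labels = NULL,
                        model_kind = c("rf", "svm", "knn", "xgb"),
                        seed = 1L, ntree = 500, knn_k = 5, nrounds = 60,
                        selection = NULL) {
  model_kind <- match.arg(model_kind)
  medians <- NULL
  if (inherits(features, "feature_matrix")) {
    if (is.null(labels)) labels <- features$labels
    medians <- features$medians
    features <- features$features
  }
  x <- as.matrix(features)
  if (nrow(x) == 0) stop("empty feature matrix")
  if (is.null(labels)) stop("labels required for training")
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  if (length(unique(y[!is.na(y)])) < 2) stop("training labels contain a single class")
  if (!all(is.finite(x))) stop("features contain non-finite values; impute first")
  if (!is.null(selection)) x <- x[, selection, drop = FALSE]

  fit <- switch(model_kind,
    rf = with_seed(seed, randomForest::randomForest(x, y, ntree = ntree)),
    svm = with_seed(seed, e1071::svm(x, y, kernel = "radial")),
    knn = list(train_x = x, train_y = y, k = knn_k),
    xgb = with_seed(seed, xgboost::xgboost(
      x = x, y = y, nrounds = nrounds, nthreads = 1, verbosity = 0)))

  structure(list(kind = model_kind, fit = fit, seed = seed,
                 feature_names = colnames(x), selection = selection,
                 impute_medians = medians),
            class = "apnea_model")
}

#' @export
print.apnea_model <- function(x, ...) {
  cat(sprintf("<apnea_model: %s, %d features%s>\n", x$kind,
              length(x$feature_names),
              if (is.null(x$selection)) "" else " (selected)"))
  invisible(x)
}

#' Predict apnea labels for new windows
#'
#' @param object An `apnea_model`.
#' @param newdata Numeric feature matrix (same column order as training) or a
#'   `feature_matrix`.
#' @param ... Unused.
#' @return Factor of 0/1 window decisions.
#' @export
predict.apnea_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$features
  x <- as.matrix(newdata)
  if (!is.null(object$selection)) x <- x[, object$selection, drop = FALSE]
  colnames(x) <- object$feature_names
  out <- switch(object$kind,
    rf = predict(object$fit, x),
    svm = predict(object$fit, x),
    knn = class::knn(object$fit$train_x, x, object$fit$train_y,
                     k = object$fit$k),
    xgb = factor(as.integer(predict(object$fit, x) > 0.5), levels = c(0L, 1L)))
  factor(out, levels = c("0", "1"))
}

#' Confusion counts and screening metrics
#'
#' Builds TP/TN/FP/FN from predicted and true window labels (positive class =
#' apnea = 1) and computes sensitivity `Se = TP/(TP+FN)`, specificity
#' `Sp = TN/(TN+FP)` and accuracy `Acc = (TP+TN)/(TP+FP+TN+FN)`. A metric
#' whose denominator is zero is returned as `NA`.
#'
#' @param predictions Predicted 0/1 labels (factor or numeric).
#' @param truth True 0/1 labels, same length.
#' @return List with `confusion` (named TP/TN/FP/FN counts) and `metrics`
#'   (named accuracy/sensitivity/specificity).
#' @examples
#' evaluate_predictions(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
evaluate_predictions <- function(predictions, truth) {
  p <- as.integer(as.character(predictions))
  t0 <- as.integer(as.character(truth))
  if (length(p) != length(t0)) stop("predictions and truth differ in length")
  tp <- sum(p == 1 & t0 == 1); tn <- sum(p == 0 & t0 == 0)
  fp <- sum(p == 1 & t0 == 0); fn <- sum(p == 0 & t0 == 1)
  total <- tp + tn + fp + fn
  if (total == 0) stop("no observations to evaluate")
  met <- c(accuracy = (tp + tn) / total,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  list(confusion = c(TP = tp, TN = tn, FP = fp, FN = fn), metrics = met)
}

#' Benchmark the comparator models
#'
#' Stratified 70/30 train/test split under a fixed seed; each model kind is
#' trained on the same split and scored with [evaluate_predictions()], with
#' wall-clock training+prediction time recorded.
#'
#' @param features Feature matrix or `feature_matrix`.
#' @param labels Binary labels (taken from `features` when omitted).
#' @param model_kinds Models to run.
#' @param seed Split / training seed.
#' @param train_frac Training fraction (default 0.7).
#' @return `data.frame` with one row per model: accuracy, sensitivity,
#'   specificity, runtime_s.
#' @export
benchmark_models <- function(features, labels = NULL,
                             model_kinds = c("rf", "svm", "knn", "xgb"),
                             seed = 1L, train_frac = 0.7) {
  if (inherits(features, "feature_matrix")) {
    if (is.null(labels)) labels <- features$labels
    features <- features$features
  }
  x <- as.matrix(features)
  if (nrow(x) == 0) stop("empty feature matrix")
  y <- as.integer(labels)
  idx_train <- with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      k <- which(y == cl)
      sample(k, max(1, round(train_frac * length(k))))
    }))
  })
  idx_test <- setdiff(seq_len(nrow(x)), idx_train)
  if (length(idx_test) == 0) stop("test split is empty")
  rows <- lapply(model_kinds, function(kind) {
    t0 <- proc.time()[["elapsed"]]
    fit <- train_model(x[idx_train, , drop = FALSE], y[idx_train],
                       model_kind = kind, seed = seed)
    pred <- predict(fit, x[idx_test, , drop = FALSE])
    dt <- proc.time()[["elapsed"]] - t0
    ev <- evaluate_predictions(pred, y[idx_test])
    data.frame(model = kind,
               accuracy = ev$metrics[["accuracy"]],
               sensitivity = ev$metrics[["sensitivity"]],
               specificity = ev$metrics[["specificity"]],
               runtime_s = dt)
  })
  do.call(rbind, rows)
}
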