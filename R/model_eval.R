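# Random-forest training, stratified 10-fold cross-validation, confusion
# metrics and impurity-based feature importance.

#' Confusion matrix from truth and predictions
#'
#' @param truth 0/1 vector of actual labels.
#' @param pred 0/1 vector of predicted labels.
#' @return list with integer `TP`, `FN`, `FP`, `TN` (class
#'   `confusion_matrix`).
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(TP = sum(truth == 1 & pred == 1),
                 FN = sum(truth == 1 & pred == 0),
                 FP = sum(truth == 0 & pred == 1),
                 TN = sum(truth == 0 & pred == 0)),
            class = "confusion_matrix")
}

cm_sum <- function(cms) {
  cell <- function(k) as.integer(sum(vapply(cms, `[[`, integer(1), k)))
  structure(list(TP = cell("TP"), FN = cell("FN"),
                 FP = cell("FP"), TN = cell("TN")),
            class = "confusion_matrix")
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Accuracy = (TP+TN)/(TP+FP+FN+TN), Precision = TP/(TP+FP), Recall =
#' TP/(TP+FN), F1 = harmonic mean of precision and recall. Ratios with a
#' zero denominator are reported as NA (missing), never as 0. Rounded
#' 2-decimal views are included alongside the raw values.
#'
#' @param cm a `confusion_matrix` (or list with TP, FN, FP, TN).
#' @return list with `accuracy`, `precision`, `recall`, `f1` and a
#'   `rounded` sub-list (2 dp).
#' @export
metrics_from_confusion <- function(cm) {
  total <- cm$TP + cm$FN + cm$FP + cm$TN
  if (total == 0)
    stop_dd("empty confusion matrix", class = "deceptrf_argument_error")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  accuracy <- (cm$TP + cm$TN) / total
  precision <- ratio(cm$TP, cm$TP + cm$FP)
  recall <- ratio(cm$TP, cm$TP + cm$FN)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  out <- list(accuracy = accuracy, precision = precision,
              recall = recall, f1 = f1)
  out$rounded <- lapply(out, function(v) if (is.na(v)) v else round(v, 2))
  out
}

#' Train a random-forest classifier
#'
#' CART forest with gini splits, bootstrap resampling and `mtry` features
#' per node; deterministic under `seed` (the fit does not touch R's RNG).
#' Hyperparameter defaults: 100 trees, unlimited depth, sqrt(p) features
#' per split.
#'
#' @param x feature matrix or data.frame (numeric, no NAs).
#' @param y 0/1 labels (numeric, logical or 2-level factor).
#' @param num_trees number of trees.
#' @param mtry features per split (default `floor(sqrt(p))`).
#' @param min_node minimum node size to attempt a split on.
#' @param max_depth maximum depth (0 = unlimited).
#' @param seed RNG seed for the forest.
#' @return a `dd_forest` model handle.
#' @export
train_classifier <- function(x, y, num_trees = 100, mtry = NULL,
                             min_node = 1, max_depth = 0, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x))
    stop_dd("training features contain missing values; run drop_missing first",
            class = "deceptrf_argument_error")
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop_dd("training data contains a single class",
            class = "deceptrf_training_error")
  stopifnot(all(y %in% c(0L, 1L)), length(y) == nrow(x))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- .rf_train_cpp(x, y, as.integer(num_trees), as.integer(mtry),
                       as.integer(min_node), as.integer(max_depth),
                       as.double(seed))
  structure(list(forest = fit, feature_names = colnames(x),
                 num_trees = num_trees, mtry = mtry, seed = seed),
            class = "dd_forest")
}

#' Predict from a trained forest
#'
#' @param object a `dd_forest`.
#' @param newdata feature matrix/data.frame with the training columns.
#' @param type `"class"` (majority vote, 0/1) or `"prob"` (fraction of
#'   trees voting 1).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.dd_forest <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  if (!is.null(object$feature_names)) {
    if (!all(object$feature_names %in% names(newdata)))
      stop_dd("feature columns of the test data do not match the model (missing: %s)",
              paste(setdiff(object$feature_names, names(newdata)),
                    collapse = ", "),
              class = "deceptrf_schema_error")
    newdata <- newdata[object$feature_names]
  }
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  p <- .rf_predict_cpp(object$forest, x)
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
print.dd_forest <- function(x, ...) {
  cat(sprintf("<dd_forest> %d trees, mtry %d, %d features, seed %s\n",
              x$num_trees, x$mtry, length(x$feature_names), format(x$seed)))
  invisible(x)
}

make_stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

make_grouped_folds <- function(groups, k, seed) {
  ug <- unique(groups)
  withr::with_seed(seed, {
    gf <- sample(rep_len(seq_len(k), length(ug)))
  })
  gf[match(groups, ug)]
}

#' Stratified 10-fold cross-validation
#'
#' Shuffled stratified frame-wise folds by default (each row tested
#' exactly once, per-fold class ratio within one row of balance). This is
#' faithful to frame-shuffled evaluation of video data but leaks
#' temporally adjacent frames between train and test; `fold_mode =
#' "grouped"` assigns whole groups (e.g. utterance windows / time
#' segments) to folds for leakage-free evaluation. Generalization metrics
#' come from the pooled (summed) fold confusion matrix, so the counts are
#' on the scale of the full dataset.
#'
#' @param features numeric feature data.frame/matrix.
#' @param labels 0/1 vector.
#' @param k number of folds (default 10).
#' @param seed seed for fold assignment; fold f trains with `seed + f`.
#' @param fold_mode `"frame"` or `"grouped"`.
#' @param groups group id per row (required for grouped mode).
#' @param ... passed to [train_classifier()].
#' @return a `dd_cv` list: `pooled` confusion, `metrics` (pooled),
#'   `fold_metrics`, `fold_confusions`, `models`, `folds`.
#' @export
cross_validate_10fold <- function(features, labels, k = 10, seed = 1L,
                                  fold_mode = c("frame", "grouped"),
                                  groups = NULL, ...) {
  fold_mode <- match.arg(fold_mode)
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  if (min(table(labels)) < k)
    stop_dd("need at least %d rows per class for %d-fold CV", k, k,
            class = "deceptrf_argument_error")
  folds <- if (fold_mode == "frame") {
    make_stratified_folds(labels, k, seed)
  } else {
    if (is.null(groups))
      stop_dd("grouped fold mode needs 'groups'", class = "deceptrf_argument_error")
    make_grouped_folds(groups, k, seed)
  }
  models <- vector("list", k)
  fold_cms <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2 || !any(!tr)) {
      fold_cms[[f]] <- structure(list(TP = 0L, FN = 0L, FP = 0L, TN = 0L),
                                 class = "confusion_matrix")
      next
    }
    models[[f]] <- train_classifier(features[tr, , drop = FALSE], labels[tr],
                                    seed = seed + f, ...)
    pred <- predict(models[[f]], features[!tr, , drop = FALSE])
    fold_cms[[f]] <- confusion_matrix(labels[!tr], pred)
  }
  pooled <- cm_sum(fold_cms)
  structure(list(pooled = pooled,
                 metrics = metrics_from_confusion(pooled),
                 fold_confusions = fold_cms,
                 fold_metrics = lapply(fold_cms, function(cm) {
                   if (cm$TP + cm$FN + cm$FP + cm$TN == 0) NULL
                   else metrics_from_confusion(cm)
                 }),
                 models = models, folds = folds, fold_mode = fold_mode,
                 seed = seed),
            class = "dd_cv")
}

#' @export
print.dd_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<dd_cv> %d folds (%s), pooled: accuracy %.2f, precision %.2f, recall %.2f, F1 %.2f\n",
              length(x$fold_confusions), x$fold_mode, m$accuracy,
              m$precision, m$recall, m$f1))
  invisible(x)
}

#' Evaluate a trained model on a holdout set
#'
#' Single-pass evaluation without refitting (the role-play holdout
#' design: the model trained on one dataset scored on another).
#'
#' @param model a `dd_forest`.
#' @param features holdout feature table (columns must match training).
#' @param labels holdout 0/1 labels.
#' @return list with `confusion` and `metrics`.
#' @export
evaluate_holdout <- function(model, features, labels) {
  if (length(labels) == 0 || nrow(as.data.frame(features)) == 0)
    stop_dd("empty holdout set", class = "deceptrf_argument_error")
  pred <- predict(model, features)
  cm <- confusion_matrix(as.integer(labels), pred)
  list(confusion = cm, metrics = metrics_from_confusion(cm))
}

#' Impurity-based feature-importance ranking
#'
#' For a cross-validation result the per-fold forests' normalized
#' importances are averaged and renormalized; for a single forest its own
#' importance is used. Weights are >= 0, sum to 1 and are sorted
#' descending.
#'
#' @param object a `dd_cv` or `dd_forest`.
#' @return data.frame with `feature`, `importance`, sorted descending.
#' @export
feature_importance <- function(object) {
  if (inherits(object, "dd_cv")) {
    models <- Filter(Negate(is.null), object$models)
    if (length(models) == 0)
      stop_dd("no trained fold models", class = "deceptrf_state_error")
    imp <- Reduce(`+`, lapply(models, function(m) m$forest$importance)) /
      length(models)
    nms <- models[[1]]$feature_names
  } else if (inherits(object, "dd_forest")) {
    imp <- object$forest$importance
    nms <- object$feature_names
  } else {
    stop_dd("feature_importance needs a dd_cv or dd_forest",
            class = "deceptrf_state_error")
  }
  imp <- imp / sum(imp)
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = nms[ord], importance = imp[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plot an importance ranking as a horizontal bar chart
#'
#' @param importance data.frame from [feature_importance()].
#' @param file optional PNG path; when given the chart is written there.
#' @param top_n number of features shown (default 20).
#' @return `file` (or NULL), invisibly.
#' @export
plot_importance <- function(importance, file = NULL, top_n = 20) {
  sub <- head(importance, top_n)
  draw <- function() {
    op <- graphics::par(mar = c(4, 11, 2, 1), las = 1)
    on.exit(graphics::par(op))
    graphics::barplot(rev(sub$importance), names.arg = rev(sub$feature),
                      horiz = TRUE, cex.names = 0.7,
                      xlab = "importance (impurity decrease, normalized)",
                      main = "Feature importance")
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else {
    draw()
  }
  invisible(file)
}

#' Serialize a trained forest to a file
#'
#' Plain-text JSON with a version header; [load_model()] restores it.
#'
#' @param model a `dd_forest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- list(format = "deceptrf_forest", version = 1L,
                  feature_names = model$feature_names,
                  num_trees = model$num_trees, mtry = model$mtry,
                  seed = model$seed,
                  importance = model$forest$importance,
                  trees = model$forest$trees)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a forest saved by [save_model()]
#'
#' @param path file written by [save_model()].
#' @return a `dd_forest`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!identical(payload$format, "deceptrf_forest"))
    stop_dd("%s is not a deceptrf model file", path,
            class = "deceptrf_format_error")
  trees <- lapply(payload$trees, function(tr) {
    list(feature = as.integer(unlist(tr$feature)),
         threshold = as.numeric(unlist(tr$threshold)),
         left = as.integer(unlist(tr$left)),
         right = as.integer(unlist(tr$right)),
         pred = as.numeric(unlist(tr$pred)))
  })
  structure(list(forest = list(trees = trees,
                               importance = as.numeric(unlist(payload$importance)),
                               num_trees = payload$num_trees),
                 feature_names = unlist(payload$feature_names),
                 num_trees = payload$num_trees, mtry = payload$mtry,
                 seed = payload$seed),
            class = "dd_forest")
}
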