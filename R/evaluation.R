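# Evaluation: one-vs-rest confusion counts, specificity/sensitivity/
# accuracy/MCC, ROC curves, and the four validation protocols
# (self-consistency, stratified k-fold CV, jackknife, independent split).
# CV and jackknife are scored by pooling all out-of-fold predictions into
# one confusion table (per-fold accuracies are kept separately); any metric
# with a zero denominator is reported as 0.

#' One-vs-rest confusion counts
#'
#' @param y_true,y_pred equal-length label vectors over the three-class set.
#' @param positive_class the class treated as positive; the union of the
#'   other two is negative.
#' @return named integer vector `TP, TN, FP, FN`.
#' @export
ovr_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  tn <- length(y_true) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

.safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Binary metrics from confusion counts
#'
#' specificity = TN/(TN+FP); sensitivity = TP/(TP+FN);
#' accuracy = (TP+TN)/total; MCC = (TP*TN - FP*FN) /
#' sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any zero denominator yields 0.
#'
#' @param counts named vector with `TP, TN, FP, FN` (as from [ovr_counts()]).
#' @return named numeric vector `specificity, sensitivity, accuracy, mcc`.
#' @export
binary_metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion table")
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(specificity = .safe_div(tn, tn + fp),
    sensitivity = .safe_div(tp, tp + fn),
    accuracy = (tp + tn) / total,
    mcc = .safe_div(tp * tn - fp * fn, den))
}

#' ROC curve and AUC for one positive class
#'
#' Standard threshold sweep over the scores (ties grouped), trapezoid AUC.
#' With a degenerate single class present in `truth` the curve is the
#' diagonal and AUC = 0.5 by convention.
#'
#' @param truth logical (or 0/1) vector: is the sample positive?
#' @param scores numeric vector of positive-class scores.
#' @return list with `fpr`, `tpr` (monotone arrays from (0,0) to (1,1)) and
#'   `auc`.
#' @export
roc_curve <- function(truth, scores) {
  truth <- as.logical(truth)
  stopifnot(length(truth) == length(scores))
  P <- sum(truth); N <- sum(!truth)
  if (P == 0 || N == 0) {
    return(list(fpr = c(0, 1), tpr = c(0, 1), auc = 0.5))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  cut <- which(diff(s) != 0)          # group tied scores
  last <- c(cut, length(s))
  tpr <- c(0, cumsum(t)[last] / P, 1)
  fpr <- c(0, cumsum(!t)[last] / N, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

# Interpolate a ROC curve onto a fixed FPR grid (vertical averaging).
.roc_on_grid <- function(roc, grid) {
  approx(roc$fpr, roc$tpr, xout = grid, ties = max, rule = 2)$y
}

#' Score predictions into an evaluation report
#'
#' Per-class metrics use the one-vs-rest mapping (each class positive in
#' turn, the other two pooled as negative). Macro specificity/sensitivity/
#' MCC are unweighted means over classes; macro accuracy is the plain
#' multiclass fraction correct.
#'
#' @param y_true,y_pred label vectors.
#' @param scores optional probability matrix (columns in canonical class
#'   order) for ROC computation.
#' @param protocol protocol name recorded in the report.
#' @return list of class `rccc_report` with `protocol`, `n`, `y_true`,
#'   `y_pred`, `per_class`, `macro`, and (when scores given) `roc`.
#' @export
evaluate_predictions <- function(y_true, y_pred, scores = NULL,
                                 protocol = "custom") {
  y_true <- normalize_labels(y_true)
  y_pred <- normalize_labels(y_pred)
  per_class <- lapply(RCCC_CLASSES, function(cl) {
    counts <- ovr_counts(y_true, y_pred, cl)
    c(as.list(counts), as.list(binary_metrics(counts)))
  })
  names(per_class) <- RCCC_CLASSES
  macro <- c(
    specificity = mean(vapply(per_class, `[[`, 0, "specificity")),
    sensitivity = mean(vapply(per_class, `[[`, 0, "sensitivity")),
    accuracy = mean(y_true == y_pred),
    mcc = mean(vapply(per_class, `[[`, 0, "mcc"))
  )
  roc <- NULL
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    stopifnot(nrow(scores) == length(y_true), ncol(scores) == length(RCCC_CLASSES))
    roc <- lapply(seq_along(RCCC_CLASSES), function(k) {
      roc_curve(y_true == RCCC_CLASSES[k], scores[, k])
    })
    names(roc) <- RCCC_CLASSES
  }
  structure(list(protocol = protocol, n = length(y_true),
                 y_true = y_true, y_pred = y_pred,
                 per_class = per_class, macro = as.list(macro), roc = roc),
            class = "rccc_report")
}

#' Self-consistency protocol: train and evaluate on the same samples
#'
#' @param features labeled feature table.
#' @param config training configuration.
#' @return `rccc_report`.
#' @export
self_consistency <- function(features, config = train_config()) {
  model <- train(features, config)
  evaluate_predictions(features$label, predict(model, features),
                       scores = predict_proba(model, features),
                       protocol = "self_consistency")
}

# Stratified fold ids: seeded shuffle within class, then round-robin with
# the fold counter carried across classes — per-class fold counts still
# differ by at most one, and k = n yields exactly one sample per fold
# (the jackknife).
.fold_ids <- function(labels, k, seed) {
  ids <- integer(length(labels))
  set.seed(derive_seed(seed, 31L))
  counter <- 0L
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    rows <- rows[sample.int(length(rows))]
    ids[rows] <- ((counter + seq_along(rows) - 1L) %% k) + 1L
    counter <- counter + length(rows)
  }
  ids
}

# Out-of-fold prediction loop shared by k-fold CV and jackknife.
.oof_evaluate <- function(features, fold_ids, config, protocol) {
  k <- max(fold_ids)
  n <- nrow(features)
  y_pred <- character(n)
  scores <- matrix(NA_real_, n, length(RCCC_CLASSES))
  fold_acc <- numeric(k)
  fold_rocs <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- which(fold_ids == f)
    model <- train(features[-hold, , drop = FALSE], config)
    P <- predict_proba(model, features[hold, , drop = FALSE])
    y_pred[hold] <- model$classes[max.col(P, ties.method = "first")]
    scores[hold, ] <- P
    fold_acc[f] <- mean(y_pred[hold] == features$label[hold])
    if (length(hold) > 1) {
      fold_rocs[[f]] <- lapply(seq_along(RCCC_CLASSES), function(kk) {
        roc_curve(features$label[hold] == RCCC_CLASSES[kk], P[, kk])
      })
    }
  }
  report <- evaluate_predictions(features$label, y_pred, scores = scores,
                                 protocol = protocol)
  report$per_fold_accuracy <- fold_acc
  # Mean ROC over folds by vertical averaging on a fixed 101-point FPR grid
  # (only meaningful when folds hold more than one sample).
  have <- !vapply(fold_rocs, is.null, logical(1))
  if (any(have)) {
    grid <- seq(0, 1, length.out = 101)
    report$mean_roc <- lapply(seq_along(RCCC_CLASSES), function(kk) {
      tprs <- vapply(fold_rocs[have],
                     function(fr) .roc_on_grid(fr[[kk]], grid), numeric(101))
      mean_tpr <- rowMeans(tprs)
      list(fpr = grid, tpr = mean_tpr,
           auc = sum(diff(grid) * (head(mean_tpr, -1) + tail(mean_tpr, -1)) / 2))
    })
    names(report$mean_roc) <- RCCC_CLASSES
  }
  report
}

#' Stratified k-fold cross-validation
#'
#' Each sample is predicted exactly once by a model that never saw it; the
#' pooled out-of-fold predictions are scored once. Per-fold accuracies and
#' a vertically averaged mean ROC are recorded as well.
#'
#' @param features labeled feature table.
#' @param k number of folds (default 10).
#' @param config training configuration.
#' @param seed seed for the fold shuffle.
#' @return `rccc_report` with `per_fold_accuracy` and `mean_roc`.
#' @export
kfold_cv <- function(features, k = 10L, config = train_config(), seed = 1L) {
  n <- nrow(features)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  .oof_evaluate(features, .fold_ids(features$label, k, seed), config,
                protocol = sprintf("%d_fold_cv", as.integer(k)))
}

#' Jackknife (leave-one-out) validation
#'
#' k-fold CV with k = n: every sample is held out once, deterministically
#' (no fold randomness); pooled predictions are scored once.
#'
#' @param features labeled feature table (n >= 3).
#' @param config training configuration.
#' @return `rccc_report`.
#' @export
jackknife <- function(features, config = train_config()) {
  n <- nrow(features)
  if (n < 3) stop("jackknife requires at least 3 samples")
  .oof_evaluate(features, seq_len(n), config, protocol = "jackknife")
}

#' Independent-split validation
#'
#' Stratified train/test split, training from scratch on the training
#' partition and reporting metrics on the held-out partition only.
#'
#' @param features labeled feature table.
#' @param train_fraction training fraction (default 0.7).
#' @param config training configuration.
#' @param seed seed for the split.
#' @return `rccc_report`.
#' @export
independent_test <- function(features, train_fraction = 0.7,
                             config = train_config(), seed = 1L) {
  split <- stratified_split(features, train_fraction, seed)
  model <- train(split$train, config)
  report <- evaluate_predictions(
    split$test$label, predict(model, split$test),
    scores = predict_proba(model, split$test),
    protocol = "independent_test")
  report$n_train <- nrow(split$train)
  report
}

#' Serialize an evaluation report to JSON (lossless round-trip)
#'
#' @param report `rccc_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(obj, class = "rccc_report")
}

#' Summarize a report as one table row per class plus the macro row
#'
#' Column order follows the method's reporting convention:
#' Specificity, Sensitivity, Accuracy, MCC.
#'
#' @param report `rccc_report`.
#' @return data.frame with rows for the three classes and `macro`.
#' @export
report_summary <- function(report) {
  rows <- c(report$per_class, list(macro = report$macro))
  data.frame(
    class = names(rows),
    Specificity = vapply(rows, function(r) as.numeric(r$specificity), 0),
    Sensitivity = vapply(rows, function(r) as.numeric(r$sensitivity), 0),
    Accuracy = vapply(rows, function(r) as.numeric(r$accuracy), 0),
    MCC = vapply(rows, function(r) as.numeric(r$mcc), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
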