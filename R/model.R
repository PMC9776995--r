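# User-facing training/prediction surface for the three-class classifiers.
# Histogram gradient boosting is the final deployed model; the others form
# the comparison suite. All hyperparameters not fixed by the method
# description live in one place (train_config defaults) so runs are pinned.

RCCC_ALGORITHMS <- c("hist_gradient_boosting", "gradient_boosting",
                     "random_forest", "decision_tree", "naive_bayes",
                     "neural_net")

#' Training configuration
#'
#' Builds a configuration with per-algorithm pinned defaults. The only
#' method-mandated values are the neural network's iteration cap (3000)
#' and early stopping; everything else is a documented engine default.
#'
#' @param algorithm one of `hist_gradient_boosting`, `gradient_boosting`,
#'   `random_forest`, `decision_tree`, `naive_bayes`, `neural_net`.
#' @param max_iterations iteration cap for iterative algorithms. Defaults:
#'   3000 for `neural_net`, 100 for the boosting variants.
#' @param early_stopping monitor a validation holdout and stop when it
#'   stalls (iterative algorithms only). `TRUE`, `FALSE`, or `"auto"`.
#'   Defaults follow the documented behavior of the delegated reference
#'   implementations: `"auto"` for `hist_gradient_boosting` (enabled only
#'   above 10000 training samples), `TRUE` for `neural_net` (the method
#'   trains the network with early stopping), `FALSE` otherwise.
#' @param validation_fraction fraction held out for early stopping, in
#'   (0, 0.5]. Default 0.1.
#' @param seed integer pipeline seed; per-component RNG streams are derived
#'   from it.
#' @param ... engine overrides (`learning_rate`, `max_depth`, `max_bins`,
#'   `min_leaf`, `n_trees`, `mtry`, `hidden`, `patience`, `lambda`).
#' @return object of class `rccc_train_config`.
#' @export
train_config <- function(algorithm = "hist_gradient_boosting",
                         max_iterations = NULL, early_stopping = NULL,
                         validation_fraction = 0.1, seed = 1L, ...) {
  if (!algorithm %in% RCCC_ALGORITHMS) {
    stop("unknown algorithm '", algorithm, "'; expected one of: ",
         paste(RCCC_ALGORITHMS, collapse = ", "))
  }
  if (validation_fraction <= 0 || validation_fraction > 0.5) {
    stop("validation_fraction must be in (0, 0.5]")
  }
  if (is.null(max_iterations)) {
    max_iterations <- switch(algorithm, neural_net = 3000L, 100L)
  }
  if (is.null(early_stopping)) {
    early_stopping <- switch(algorithm,
                             hist_gradient_boosting = "auto",
                             neural_net = TRUE,
                             FALSE)
  }
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  defaults <- list(
    learning_rate = switch(algorithm, neural_net = 0.01, 0.1),
    max_depth = switch(algorithm,
                       hist_gradient_boosting = 4L,
                       gradient_boosting = 3L,
                       20L),
    max_bins = switch(algorithm, hist_gradient_boosting = 64L, 256L),
    min_leaf = switch(algorithm,
                      hist_gradient_boosting = 5L,
                      gradient_boosting = 5L,
                      1L),
    n_trees = 100L,
    mtry = NULL,
    hidden = 12L,
    patience = switch(algorithm, neural_net = 25L, 10L),
    lambda = 1e-3
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config option(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  structure(c(list(algorithm = algorithm, max_iterations = max_iterations,
                   early_stopping = early_stopping,
                   validation_fraction = validation_fraction,
                   seed = as.integer(seed)),
              defaults),
            class = "rccc_train_config")
}

.feature_matrix <- function(features) {
  missing <- setdiff(.feature_cols, names(features))
  if (length(missing) > 0) {
    stop("feature rows must carry exactly the 6 feature columns; missing: ",
         paste(missing, collapse = ", "))
  }
  X <- as.matrix(features[, .feature_cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite feature values")
  X
}

#' Train a three-class classifier on a feature table
#'
#' @param features data.frame with the six feature columns and a `label`
#'   column over the three-class vocabulary (see [RCCC_CLASSES]).
#' @param config configuration from [train_config()].
#' @return object of class `rccc_model` with elements `algorithm`,
#'   `classes` (fixed canonical order), `fitted_state`,
#'   `training_history` (iterative algorithms; NULL otherwise), and `seed`.
#' @export
train <- function(features, config = train_config()) {
  if (!inherits(config, "rccc_train_config")) {
    stop("config must come from train_config()")
  }
  X <- .feature_matrix(features)
  if (!"label" %in% names(features) || anyNA(features$label)) {
    stop("training features must be labeled")
  }
  labels <- normalize_labels(features$label)
  if (length(unique(labels)) < 2) {
    stop("training requires at least 2 classes (got 1)")
  }
  classes <- RCCC_CLASSES
  y <- match(labels, classes)
  K <- length(classes)
  early <- config$early_stopping
  if (identical(early, "auto")) early <- nrow(X) > 10000
  set.seed(derive_seed(config$seed, 11L))
  state <- switch(
    config$algorithm,
    hist_gradient_boosting = ,
    gradient_boosting = fit_gboost(
      X, y, K, max_iter = config$max_iterations,
      learning_rate = config$learning_rate, max_depth = config$max_depth,
      min_leaf = config$min_leaf, max_bins = config$max_bins,
      lambda = config$lambda, early_stopping = early,
      validation_fraction = config$validation_fraction,
      patience = config$patience, seed = config$seed),
    random_forest = fit_forest(
      X, y, K, n_trees = config$n_trees, mtry = config$mtry,
      max_depth = config$max_depth, min_leaf = config$min_leaf),
    decision_tree = fit_cart(
      X, y, K, max_depth = config$max_depth, min_leaf = config$min_leaf),
    naive_bayes = fit_gnb(X, y, K),
    neural_net = fit_mlp(
      X, y, K, hidden = config$hidden, max_iter = config$max_iterations,
      learning_rate = config$learning_rate,
      early_stopping = isTRUE(early),
      validation_fraction = config$validation_fraction,
      patience = config$patience, seed = config$seed)
  )
  structure(list(algorithm = config$algorithm, classes = classes,
                 fitted_state = state,
                 training_history = state$history,
                 seed = config$seed, config = config),
            class = "rccc_model")
}

#' Per-class prediction probabilities
#'
#' @param model fitted `rccc_model`.
#' @param features feature table (labels optional).
#' @return numeric matrix, one row per sample, columns named by
#'   `model$classes`; rows sum to 1.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "rccc_model"))
  X <- .feature_matrix(features)
  P <- switch(model$algorithm,
              hist_gradient_boosting = ,
              gradient_boosting = predict_gboost(model$fitted_state, X),
              random_forest = predict_forest(model$fitted_state, X),
              decision_tree = predict_cart(model$fitted_state, X),
              naive_bayes = predict_gnb(model$fitted_state, X),
              neural_net = predict_mlp(model$fitted_state, X))
  P <- P / rowSums(P)
  colnames(P) <- model$classes
  P
}

#' Predict class labels
#'
#' The label is the argmax of [predict_proba()] (first class wins ties, in
#' canonical class order).
#'
#' @param object fitted `rccc_model`.
#' @param features feature table.
#' @param ... unused.
#' @return character vector of labels drawn from `object$classes`.
#' @export
predict.rccc_model <- function(object, features, ...) {
  P <- predict_proba(object, features)
  object$classes[max.col(P, ties.method = "first")]
}

#' Save / load a fitted model with a format-version header
#'
#' @param model fitted `rccc_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rccc_model"))
  saveRDS(list(format = "rcccpred-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "rcccpred-model")) {
    stop("not an rcccpred model file: ", path)
  }
  if (obj$version != 1L) stop("unsupported model format version ", obj$version)
  obj$model
}
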