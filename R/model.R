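# Random-forest training and scoring behind a pluggable binary-classifier
# seam. The forest itself is implemented in src/rforest.cpp because no
# random-forest package can be assumed at run time; it is a conventional
# bagged CART ensemble with Gini splits and per-node feature subsampling,
# driven by its own seeded RNG so results are reproducible across platforms.

#' Random forest configuration
#'
#' The study's classifier configuration: 100 trees grown from bootstrap
#' samples with a fixed seed of 1. Remaining growth controls default to the
#' standard classification choices (`mtry = floor(sqrt(p))`, minimum node
#' size 1, generous depth cap) and are stored with the model for
#' reproducibility.
#'
#' @param n_trees number of trees (default 100).
#' @param seed integer RNG seed for bootstrap and feature subsampling
#'   (default 1).
#' @param mtry features tried per split; `NULL` (default) means
#'   `floor(sqrt(ncol(X)))`, resolved at fit time.
#' @param min_leaf minimum samples in a node for it to be split further.
#' @param max_depth depth cap for tree growth.
#' @param vote if `TRUE`, scores are hard-vote fractions (each tree votes its
#'   leaf's majority class); default `FALSE` averages leaf class
#'   probabilities, which yields smoother ROC curves. Both are consistent
#'   with aggregation "according to voting rules".
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100L, seed = 1L, mtry = NULL,
                      min_leaf = 1L, max_depth = 30L, vote = FALSE) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("n_trees must be >= 1")
  structure(list(n_trees = n_trees, seed = as.integer(seed),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 vote = isTRUE(vote)),
            class = "rf_config")
}

MODEL_FORMAT_VERSION <- "sixmApred-rf/1"

#' Train a random forest
#'
#' Fits `config$n_trees` CART trees on bootstrap resamples of the rows of
#' `X`, with `mtry` features considered at each split. Deterministic for
#' fixed `(X, y, config)` including the seed.
#'
#' @param X numeric feature matrix with column names (one row per sample).
#' @param y binary labels (0/1), both classes present.
#' @param config an [rf_config()].
#' @return an object of class `m6a_model` holding the fitted forest, the
#'   feature names it was trained on, and training metadata.
#' @export
train_model <- function(X, y, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) < 2L) stop("need at least 2 training rows")
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (anyNA(X) || any(!is.finite(X))) stop("X contains NA/NaN/Inf")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))

  mtry <- if (is.null(config$mtry)) {
    max(1L, as.integer(floor(sqrt(ncol(X)))))
  } else {
    config$mtry
  }
  forest <- rf_fit_cpp(X, y, config$n_trees, mtry, config$min_leaf,
                       config$max_depth, config$seed)
  structure(list(
    format = MODEL_FORMAT_VERSION,
    config = config,
    mtry = mtry,
    feature_names = colnames(X),
    forest = forest,
    n_pos = sum(y == 1L), n_neg = sum(y == 0L),
    scheme = attr(X, "scheme") %||% NA_character_
  ), class = "m6a_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.m6a_model <- function(x, ...) {
  cat("<m6a_model> random forest:", x$config$n_trees, "trees, mtry",
      x$mtry, ", seed", x$config$seed, "\n")
  cat("  features:", length(x$feature_names),
      if (!is.na(x$scheme)) paste0("(", x$scheme, ")") else "", "\n")
  cat("  trained on", x$n_pos, "positive /", x$n_neg, "negative samples\n")
  invisible(x)
}

check_features <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(model$feature_names)) {
      stop("feature matrix has ", ncol(X), " columns; model expects ",
           length(model$feature_names))
    }
    colnames(X) <- model$feature_names
    return(X)
  }
  missing <- setdiff(model$feature_names, colnames(X))
  extra <- setdiff(colnames(X), model$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature mismatch; missing: ",
         paste(utils::head(missing, 3L), collapse = ", "),
         if (length(missing) > 3L) ", ..." else "",
         "; extra: ", paste(utils::head(extra, 3L), collapse = ", "),
         if (length(extra) > 3L) ", ..." else "")
  }
  X[, model$feature_names, drop = FALSE]
}

#' Score samples with a trained model
#'
#' @param model an `m6a_model`.
#' @param X feature matrix whose columns match `model$feature_names` (any
#'   column order; matched by name).
#' @return numeric scores in `[0, 1]`, one per row: the mean predicted
#'   class-1 probability across trees (or the vote fraction if the model was
#'   configured with `vote = TRUE`).
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "m6a_model"))
  X <- check_features(model, X)
  rf_predict_cpp(model$forest, X, model$config$vote)
}

#' Threshold scores into hard labels
#'
#' @param model an `m6a_model`.
#' @param X feature matrix.
#' @param threshold decision threshold in `(0, 1)`; a sample is called
#'   positive iff its score is `>= threshold`. Default 0.5, matching the
#'   balanced-class design.
#' @return integer 0/1 labels.
#' @export
predict_labels <- function(model, X, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  as.integer(predict_scores(model, X) >= threshold)
}

#' Save / load a trained model
#'
#' Models are serialized with a format-version string that is checked on
#' load, so stale or truncated files fail cleanly. Round-tripping a model
#' yields bit-identical predictions.
#'
#' @param model an `m6a_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "m6a_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt model file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT_VERSION)) {
    stop("'", path, "' is not a ", MODEL_FORMAT_VERSION, " model file")
  }
  class(obj) <- "m6a_model"
  obj
}

#' Classifier seam
#'
#' Evaluation drivers accept any object of class `m6a_classifier`: a list
#' with `fit(X, y)` returning an opaque fitted object and
#' `score(fitted, X)` returning numeric scores in `[0, 1]`.
#' [rf_classifier()] wraps the bundled random forest;
#' [threshold_classifier()] is a trivial single-feature scorer used to test
#' the seam.
#'
#' @param config an [rf_config()].
#' @return an `m6a_classifier`.
#' @export
rf_classifier <- function(config = rf_config()) {
  structure(list(
    name = "random_forest",
    config = config,
    fit = function(X, y) train_model(X, y, config),
    score = function(fitted, X) predict_scores(fitted, X)
  ), class = "m6a_classifier")
}

#' @rdname rf_classifier
#' @param feature column (name or index) whose standardized value is used
#'   directly as the score.
#' @export
threshold_classifier <- function(feature = 1L) {
  structure(list(
    name = "threshold",
    config = NULL,
    fit = function(X, y) {
      v <- X[, feature]
      list(feature = feature, lo = min(v), hi = max(v))
    },
    score = function(fitted, X) {
      v <- X[, fitted$feature]
      span <- fitted$hi - fitted$lo
      if (span <= 0) return(rep(0.5, length(v)))
      pmin(1, pmax(0, (v - fitted$lo) / span))
    }
  ), class = "m6a_classifier")
}
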