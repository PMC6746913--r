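# Threshold metrics (Sn, Sp, Acc, MCC), ROC/AUC, and the evaluation
# protocols: stratified k-fold cross-validation with pooled out-of-fold
# scoring, ratio splits with internal-CV "training" metrics, jackknife
# (leave-one-out), and single-pass independent-test evaluation.

#' Confusion counts for binary predictions
#'
#' Counts are stored in the site-prediction convention: `n_pos`/`n_neg` are
#' the numbers of true 6mA / non-6mA samples, `fn` the 6mA samples predicted
#' as non-6mA, and `fp` the non-6mA samples predicted as 6mA.
#'
#' @param y_true,y_pred equal-length binary 0/1 vectors.
#' @return list of class `m6a_confusion` with fields `n_pos`, `n_neg`,
#'   `fn`, `fp`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  confusion_counts(n_pos = sum(y_true == 1L), n_neg = sum(y_true == 0L),
                   fn = sum(y_true == 1L & y_pred == 0L),
                   fp = sum(y_true == 0L & y_pred == 1L))
}

#' @rdname confusion
#' @param n_pos,n_neg,fn,fp counts (see above); `0 <= fn <= n_pos` and
#'   `0 <= fp <= n_neg`.
#' @export
confusion_counts <- function(n_pos, n_neg, fn, fp) {
  if (fn < 0 || fn > n_pos || fp < 0 || fp > n_neg) {
    stop("require 0 <= fn <= n_pos and 0 <= fp <= n_neg")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 fn = as.integer(fn), fp = as.integer(fp)),
            class = "m6a_confusion")
}

#' Threshold classification metrics
#'
#' Computes sensitivity `Sn = 1 - fn/n_pos`, specificity
#' `Sp = 1 - fp/n_neg`, accuracy `Acc = 1 - (fn + fp)/(n_pos + n_neg)` and
#' the Matthews correlation coefficient from the confusion counts. MCC is
#' evaluated in the standard `(TP, TN, FP, FN)` form, which is algebraically
#' identical to the rearranged ratio form used alongside Sn/Sp in the site
#' prediction literature; its range is `[-1, 1]` (all-correct = 1,
#' half-wrong per class = 0, all-wrong = -1). When any margin of the
#' confusion table is zero, MCC is reported as 0 with a warning (the ratio
#' form divides by zero there).
#'
#' @param counts an `m6a_confusion`.
#' @return list of class `m6a_metrics` with `sn`, `sp`, `acc`, `mcc` and
#'   the underlying `counts`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "m6a_confusion"))
  if (counts$n_pos == 0L || counts$n_neg == 0L) {
    stop("both classes must be non-empty")
  }
  tp <- as.double(counts$n_pos - counts$fn)
  tn <- as.double(counts$n_neg - counts$fp)
  fp <- as.double(counts$fp)
  fn <- as.double(counts$fn)
  sn <- 1 - fn / counts$n_pos
  sp <- 1 - fp / counts$n_neg
  acc <- 1 - (fn + fp) / (counts$n_pos + counts$n_neg)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) {
    warning("degenerate confusion table (zero margin); MCC reported as 0")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(den)
  }
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 auc = NULL, roc = NULL, counts = counts,
                 protocol = list()),
            class = "m6a_metrics")
}

#' @export
print.m6a_metrics <- function(x, digits = 4L, ...) {
  cat("<m6a_metrics>")
  if (length(x$protocol)) {
    cat(" [", paste(names(x$protocol), unlist(x$protocol), sep = "=",
                    collapse = ", "), "]", sep = "")
  }
  cat("\n  Sn =", round(x$sn, digits), " Sp =", round(x$sp, digits),
      " Acc =", round(x$acc, digits), " MCC =", round(x$mcc, digits))
  if (!is.null(x$auc)) cat("  AUC =", round(x$auc, digits))
  cat("\n")
  invisible(x)
}

#' ROC curve from scores
#'
#' Sweeps the decision threshold over the unique score values in descending
#' order; tied scores collapse to a single ROC point and the `(0, 0)` anchor
#' is prepended (the `(1, 1)` anchor arises at the lowest threshold).
#'
#' @param y_true binary 0/1 labels, both classes present.
#' @param scores numeric scores, higher = more positive.
#' @return `data.frame` with columns `threshold`, `fpr`, `tpr`; `fpr` is
#'   non-decreasing.
#' @export
roc_curve <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) stop("length mismatch")
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes to be present")
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]
  ss <- scores[ord]
  last_of_tie <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- cumsum(ys)[last_of_tie]
  fp <- cumsum(1L - ys)[last_of_tie]
  data.frame(threshold = c(Inf, ss[last_of_tie]),
             fpr = c(0, fp / n_neg),
             tpr = c(0, tp / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under an ROC point list; on the same data this equals
#' the Mann-Whitney rank statistic `P(score_pos > score_neg) + P(tie)/2`.
#'
#' @param roc a data frame from [roc_curve()] (or any ordered `fpr`/`tpr`
#'   point list with at least two points).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  stopifnot(is.data.frame(roc), all(c("fpr", "tpr") %in% names(roc)))
  if (nrow(roc) < 2L) stop("need at least 2 ROC points")
  dx <- diff(roc$fpr)
  my <- (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2
  sum(dx * my)
}

#' @rdname auc
#' @param y_true,scores as in [roc_curve()].
#' @export
roc_auc <- function(y_true, scores) auc(roc_curve(y_true, scores))

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, so fold class counts differ by at most 1
stratified_folds <- function(y, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (min(table(factor(y, levels = c(0L, 1L)))) < k) {
    stop("each class must have at least k = ", k, " samples")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

encode_and_labels <- function(windows, schemes, k_values, ...) {
  if (!("label" %in% names(windows)) || anyNA(windows$label)) {
    stop("windows must carry complete 0/1 labels")
  }
  X <- encode_windows(windows, schemes = schemes, k_values = k_values, ...)
  list(X = X, y = as.integer(windows$label))
}

make_report <- function(y, scores, threshold = 0.5, protocol = list()) {
  rep <- classification_metrics(confusion(y, as.integer(scores >= threshold)))
  rep$roc <- roc_curve(y, scores)
  rep$auc <- auc(rep$roc)
  rep$protocol <- protocol
  rep
}

#' Stratified k-fold cross-validation
#'
#' Partitions the labelled windows into `k` stratified folds (seeded), and
#' for each fold trains the classifier on the remaining folds and scores the
#' held-out fold. All out-of-fold scores are pooled into a single ROC/AUC,
#' and pooled hard predictions at `threshold` give one confusion table for
#' Sn/Sp/Acc/MCC — one curve and one metric set per protocol run, not
#' per-fold averages.
#'
#' @param windows labelled `m6a_windows`.
#' @param schemes encoding scheme tag(s); see [encode_windows()].
#' @param classifier an `m6a_classifier` (default the bundled random forest
#'   with 100 trees, seed 1).
#' @param k number of folds (default 5).
#' @param seed seed for the fold partition.
#' @param threshold decision threshold for the hard metrics.
#' @param k_values KNFC k sizes, if the scheme includes KNFC.
#' @return an `m6a_metrics` report with ROC, AUC and protocol metadata;
#'   the pooled out-of-fold scores are attached as attribute `"scores"` and
#'   the fold assignment as `"folds"`.
#' @export
kfold_cv <- function(windows, schemes = "MNBE",
                     classifier = rf_classifier(), k = 5L, seed = 1L,
                     threshold = 0.5, k_values = c(2L, 3L, 4L)) {
  el <- encode_and_labels(windows, schemes, k_values)
  fold <- stratified_folds(el$y, k, seed)
  scores <- numeric(length(el$y))
  for (f in seq_len(k)) {
    hold <- fold == f
    fitted <- classifier$fit(el$X[!hold, , drop = FALSE], el$y[!hold])
    scores[hold] <- classifier$score(fitted, el$X[hold, , drop = FALSE])
  }
  rep <- make_report(el$y, scores, threshold, protocol = list(
    protocol = "kfold", k = k, seed = seed,
    classifier = classifier$name, scheme = attr(el$X, "scheme")
  ))
  attr(rep, "scores") <- scores
  attr(rep, "folds") <- fold
  rep
}

#' Ratio-split evaluation
#'
#' Stratified split of the labelled windows into a training part (fraction
#' `train_fraction`) and a testing part. The classifier is fitted on the
#' training part and evaluated on the testing part; the "training" report is
#' computed by internal fivefold cross-validation on the training part
#' (plain resubstitution would be near-perfect for a random forest and
#' meaningless as a training-performance estimate).
#'
#' @inheritParams kfold_cv
#' @param train_fraction fraction of each class assigned to the training
#'   part, strictly in `(0, 1)`; e.g. 0.9 for a 9:1 split.
#' @return list with `m6a_metrics` elements `testing` and `training`.
#' @export
ratio_split_eval <- function(windows, schemes = "MNBE",
                             classifier = rf_classifier(),
                             train_fraction = 0.5, seed = 1L,
                             threshold = 0.5, k_values = c(2L, 3L, 4L)) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly inside (0, 1)")
  }
  y <- as.integer(windows$label)
  in_train <- logical(nrow(windows))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      n_tr <- round(length(idx) * train_fraction)
      if (n_tr < 1L || n_tr >= length(idx)) {
        stop("degenerate split: class ", cls, " would have ", n_tr,
             " training samples of ", length(idx))
      }
      in_train[idx[sample.int(length(idx), n_tr)]] <- TRUE
    }
  })
  train_w <- windows[in_train, , drop = FALSE]
  test_w <- windows[!in_train, , drop = FALSE]

  el_tr <- encode_and_labels(train_w, schemes, k_values)
  el_te <- encode_and_labels(test_w, schemes, k_values)
  fitted <- classifier$fit(el_tr$X, el_tr$y)
  testing <- make_report(el_te$y, classifier$score(fitted, el_te$X),
                         threshold, protocol = list(
    protocol = "ratio_split", part = "testing",
    train_fraction = train_fraction, seed = seed,
    classifier = classifier$name, scheme = attr(el_tr$X, "scheme")
  ))
  training <- kfold_cv(train_w, schemes = schemes, classifier = classifier,
                       k = 5L, seed = seed + 1L, threshold = threshold,
                       k_values = k_values)
  training$protocol <- c(list(protocol = "ratio_split", part = "training",
                              train_fraction = train_fraction),
                         training$protocol[-1L])
  list(testing = testing, training = training)
}

#' Jackknife (leave-one-out) cross-validation
#'
#' Each sample is scored by a classifier trained on all other samples; the
#' `n` held-out scores are pooled into one report. Because this costs `n`
#' fits it is capped at `cap` samples by default — use [kfold_cv()] beyond
#' desk scale.
#'
#' @inheritParams kfold_cv
#' @param cap maximum `n` without explicit override.
#' @param override set `TRUE` to run beyond `cap`.
#' @return an `m6a_metrics` report.
#' @export
jackknife_cv <- function(windows, schemes = "MNBE",
                         classifier = rf_classifier(), threshold = 0.5,
                         k_values = c(2L, 3L, 4L), cap = 2000L,
                         override = FALSE) {
  n <- nrow(windows)
  if (n > cap && !override) {
    stop("n = ", n, " exceeds the jackknife cap (", cap,
         "); use kfold_cv() or set override = TRUE")
  }
  el <- encode_and_labels(windows, schemes, k_values)
  scores <- vapply(seq_len(n), function(i) {
    fitted <- classifier$fit(el$X[-i, , drop = FALSE], el$y[-i])
    classifier$score(fitted, el$X[i, , drop = FALSE])
  }, numeric(1L))
  make_report(el$y, scores, threshold, protocol = list(
    protocol = "jackknife", n = n, classifier = classifier$name,
    scheme = attr(el$X, "scheme")
  ))
}

#' Independent-test evaluation
#'
#' Scores a held-out window set with an already-trained model (no
#' refitting) and reports metrics. The caller is responsible for the test
#' set being disjoint from training. If the test set contains a single
#' class, the ROC/AUC and MCC are omitted with a warning and only the
#' defined point metrics are returned.
#'
#' @param model a trained `m6a_model`.
#' @param windows labelled `m6a_windows` test set.
#' @param schemes encoding scheme(s); default `NULL` reuses the scheme tag
#'   stored in the model.
#' @param threshold decision threshold.
#' @param k_values KNFC k sizes, if applicable.
#' @return an `m6a_metrics` report (fields undefined for a single-class
#'   test set are `NA`).
#' @export
independent_eval <- function(model, windows, schemes = NULL,
                             threshold = 0.5, k_values = c(2L, 3L, 4L)) {
  stopifnot(inherits(model, "m6a_model"))
  if (is.null(schemes)) {
    if (is.na(model$scheme)) stop("model carries no scheme tag; pass schemes=")
    schemes <- strsplit(model$scheme, "-", fixed = TRUE)[[1L]]
  }
  if (!("label" %in% names(windows)) || anyNA(windows$label)) {
    stop("windows must carry complete 0/1 labels")
  }
  X <- encode_windows(windows, schemes = schemes, k_values = k_values)
  y <- as.integer(windows$label)
  scores <- predict_scores(model, X)
  proto <- list(protocol = "independent", n = length(y),
                scheme = attr(X, "scheme"))
  if (length(unique(y)) == 2L) {
    return(make_report(y, scores, threshold, protocol = proto))
  }
  warning("single-class test set: ROC/AUC and MCC are undefined")
  pred <- as.integer(scores >= threshold)
  acc <- mean(pred == y)
  rep <- structure(list(
    sn = if (all(y == 1L)) mean(pred == 1L) else NA_real_,
    sp = if (all(y == 0L)) mean(pred == 0L) else NA_real_,
    acc = acc, mcc = NA_real_, auc = NULL, roc = NULL,
    counts = NULL, protocol = proto
  ), class = "m6a_metrics")
  rep
}
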