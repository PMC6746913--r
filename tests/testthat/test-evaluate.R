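test_that("confusion counts match hand counts", {
  y <- c(1, 1, 0, 0)
  expect_equal(unclass(confusion(y, y))[c("fn", "fp")], list(fn = 0L, fp = 0L))
  cc <- confusion(y, 1 - y)
  expect_equal(cc$fn, 2L)
  expect_equal(cc$fp, 2L)
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc)[c("n_pos", "n_neg", "fn", "fp")],
               list(n_pos = 2L, n_neg = 2L, fn = 1L, fp = 1L))
  expect_error(confusion(c(1, 0), c(1)), "length mismatch")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
  expect_error(confusion_counts(10, 10, 11, 0), "fn")
})

test_that("metric boundary identities hold exactly", {
  m <- classification_metrics(confusion_counts(50, 50, 0, 0))
  expect_identical(m$mcc, 1)
  expect_identical(m$acc, 1)
  m <- classification_metrics(confusion_counts(100, 100, 50, 50))
  expect_identical(m$mcc, 0)
  m <- classification_metrics(confusion_counts(40, 60, 40, 60))
  expect_identical(m$mcc, -1)
  expect_equal(m$sn, 0)
  expect_equal(m$sp, 0)
  expect_error(classification_metrics(confusion_counts(0, 10, 0, 5)),
               "non-empty")
})

test_that("metric identities hold over random confusion tables", {
  set.seed(426)
  for (i in 1:200) {
    np <- sample(1:500, 1)
    nn <- sample(1:500, 1)
    fn <- sample(0:np, 1)
    fp <- sample(0:nn, 1)
    cc <- confusion_counts(np, nn, fn, fp)
    m <- suppressWarnings(classification_metrics(cc))
    expect_true(m$sn >= 0 && m$sn <= 1)
    expect_true(m$sp >= 0 && m$sp <= 1)
    expect_true(m$acc >= 0 && m$acc <= 1)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    expect_equal(m$acc, (m$sn * np + m$sp * nn) / (np + nn))
    # ratio form agrees with the standard form wherever defined
    tp <- np - fn; tn <- nn - fp
    if ((tp + fp) > 0 && (tn + fn) > 0) {
      expect_equal(m$mcc, mcc_ratio_form(np, nn, fn, fp), tolerance = 1e-12)
    }
  }
})

test_that("degenerate confusion tables give MCC 0 with a warning", {
  expect_warning(m <- classification_metrics(confusion_counts(5, 5, 5, 0)),
                 "degenerate")
  expect_identical(m$mcc, 0)
})

test_that("ROC curve shape on canonical scorers", {
  y <- c(1, 1, 1, 0, 0, 0)
  roc <- roc_curve(y, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(auc(roc), 1)

  # constant scores collapse to anchors; AUC 1/2
  roc <- roc_curve(y, rep(0.5, 6))
  expect_equal(nrow(roc), 2L)
  expect_equal(roc$fpr, c(0, 1))
  expect_equal(roc$tpr, c(0, 1))
  expect_equal(auc(roc), 0.5)

  # antisymmetry under score negation
  set.seed(427)
  s <- runif(40)
  y2 <- rbinom(40, 1, 0.5)
  y2[1:2] <- c(0, 1)
  expect_equal(roc_auc(y2, -s), 1 - roc_auc(y2, s))

  expect_error(roc_curve(rep(1, 5), runif(5)), "both classes")
  expect_error(auc(data.frame(fpr = 0, tpr = 0)), "2 ROC points")
})

test_that("trapezoidal AUC equals the exhaustive rank-count oracle", {
  set.seed(428)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    y <- integer(n)
    y[sample(n, sample(1:(n - 1), 1))] <- 1L
    s <- sample(round(runif(n), 2))  # coarse scores force ties
    expect_equal(roc_auc(y, s), auc_oracle(y, s), tolerance = 1e-12)
  }
})

test_that("shuffled labels give null AUC", {
  set.seed(429)
  n <- 4000
  y <- rep(c(0L, 1L), n / 2)
  s <- runif(n)
  # 3-sigma band around 1/2: sd(AUC) ~ sqrt(n+1)/sqrt(12*n_pos*n_neg)
  expect_lt(abs(roc_auc(y, s) - 0.5), 3 * sqrt((n + 1) / (12 * (n / 2)^2)))
})

test_that("kfold partitions are stratified exact partitions", {
  set.seed(430)
  w <- generate_windows(synthetic_spec(n_pos = 60, n_neg = 40, seed = 2))
  clf <- threshold_classifier("MNBE_p13_A")
  rep <- kfold_cv(w, classifier = clf, k = 5, seed = 3)
  fold <- attr(rep, "folds")
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(attr(rep, "scores"), 100L)  # every sample scored once
  for (f in 1:5) {
    expect_equal(sum(w$label == 1 & fold == f), 12)
    expect_equal(sum(w$label == 0 & fold == f), 8)
  }
  # same seed, same partition and report
  rep2 <- kfold_cv(w, classifier = clf, k = 5, seed = 3)
  expect_identical(attr(rep2, "folds"), fold)
  expect_identical(rep2$auc, rep$auc)
  expect_error(kfold_cv(w[1:8, ], k = 5, seed = 1), "at least k")
})

test_that("kfold CV recovers signal and stays null on noise (small n)", {
  w <- generate_windows(synthetic_spec(n_pos = 150, n_neg = 150,
                                       bias_strength = 0.8, seed = 31))
  clf <- rf_classifier(rf_config(n_trees = 40))
  rep <- kfold_cv(w, classifier = clf, k = 5, seed = 1)
  expect_gt(rep$auc, 0.85)
  w0 <- generate_windows(synthetic_spec(n_pos = 150, n_neg = 150,
                                        bias_strength = 0, seed = 32))
  rep0 <- kfold_cv(w0, classifier = clf, k = 5, seed = 1)
  expect_lt(abs(rep0$auc - 0.5), 0.12)
})

test_that("ratio split is a stratified partition with internal-CV training metrics", {
  w <- generate_windows(synthetic_spec(n_pos = 100, n_neg = 100, seed = 33))
  clf <- threshold_classifier("MNBE_p13_A")
  out <- ratio_split_eval(w, classifier = clf, train_fraction = 0.7,
                          seed = 2)
  expect_named(out, c("testing", "training"))
  expect_equal(out$testing$counts$n_pos + out$testing$counts$n_neg, 60L)
  expect_equal(out$training$protocol$part, "training")
  expect_equal(out$training$protocol$protocol, "ratio_split")
  # determinism
  out2 <- ratio_split_eval(w, classifier = clf, train_fraction = 0.7,
                           seed = 2)
  expect_identical(out$testing$auc, out2$testing$auc)
  expect_error(ratio_split_eval(w, train_fraction = 1.0), "train_fraction")
  expect_error(ratio_split_eval(w[1:4, ], train_fraction = 0.9), "degenerate")
})

test_that("jackknife equals n-fold CV definitionally and respects its cap", {
  w <- generate_windows(synthetic_spec(n_pos = 30, n_neg = 30,
                                       bias_strength = 1, seed = 34))
  clf <- threshold_classifier("MNBE_p13_A")
  rep <- jackknife_cv(w, classifier = clf)
  expect_equal(rep$protocol$protocol, "jackknife")
  expect_equal(rep$protocol$n, 60L)
  # definitional check: pooled scores equal a direct leave-one-out loop
  X <- encode_windows(w)
  y <- w$label
  loo <- vapply(seq_len(nrow(X)), function(i) {
    fitted <- clf$fit(X[-i, , drop = FALSE], y[-i])
    clf$score(fitted, X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(rep$auc, roc_auc(y, loo), tolerance = 1e-12)
  expect_error(jackknife_cv(w, cap = 10), "cap")
  expect_silent(r2 <- jackknife_cv(w, classifier = clf, cap = 10,
                                   override = TRUE))
  expect_equal(r2$auc, rep$auc)
})

test_that("jackknife with the forest separates an easy fixture", {
  w <- generate_windows(synthetic_spec(n_pos = 50, n_neg = 50,
                                       bias_strength = 1, seed = 35))
  rep <- jackknife_cv(w, classifier = rf_classifier(rf_config(n_trees = 30)))
  expect_gte(rep$acc, 0.9)
})

test_that("independent evaluation matches manual composition and handles one class", {
  train_w <- generate_windows(synthetic_spec(n_pos = 150, n_neg = 150,
                                             bias_strength = 0.9, seed = 36))
  test_w <- generate_windows(synthetic_spec(n_pos = 80, n_neg = 80,
                                            bias_strength = 0.9, seed = 37))
  X <- encode_windows(train_w)
  model <- train_model(X, train_w$label, rf_config(n_trees = 40))
  rep <- independent_eval(model, test_w)
  expect_gt(rep$auc, 0.85)

  # composition identity: metrics == metrics(confusion(manual))
  Xt <- encode_windows(test_w)
  manual <- classification_metrics(
    confusion(test_w$label, predict_labels(model, Xt)))
  expect_equal(rep$sn, manual$sn)
  expect_equal(rep$sp, manual$sp)
  expect_equal(rep$acc, manual$acc)
  expect_equal(rep$mcc, manual$mcc)

  # sanity path: evaluating on training data of a near-separable fit
  rep_tr <- independent_eval(model, train_w)
  expect_gt(rep_tr$acc, 0.99)

  # single-class test set: point metrics only, with a warning
  pos_only <- test_w[test_w$label == 1L, ]
  expect_warning(rep1 <- independent_eval(model, pos_only), "single-class")
  expect_true(is.finite(rep1$sn))
  expect_true(is.na(rep1$mcc))
  expect_null(rep1$auc)
})
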