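R <- "kidney_tumor_driver"; O <- "other_tumor_driver"; U <- "unknown"

test_that("one-vs-rest counts enumerate the confusion table", {
  y_true <- c(R, O, U, R)
  y_pred <- c(R, U, U, O)
  expect_equal(ovr_counts(y_true, y_pred, R),
               c(TP = 1L, TN = 2L, FP = 0L, FN = 1L))
  # perfect predictions: no confusion anywhere
  for (cl in RCCC_CLASSES) {
    cnt <- ovr_counts(y_true, y_true, cl)
    expect_equal(cnt[["FP"]] + cnt[["FN"]], 0)
  }
  # partition identity: sum of per-class TP = number correct
  tp_sum <- sum(vapply(RCCC_CLASSES,
                       function(cl) ovr_counts(y_true, y_pred, cl)[["TP"]], 0))
  expect_equal(tp_sum, sum(y_true == y_pred))
  expect_error(ovr_counts(y_true, y_pred[1:2], R), "equal length")
})

test_that("binary metrics match the hand-evaluated definitions", {
  m <- binary_metrics(c(TP = 2, TN = 3, FP = 1, FN = 0))
  expect_equal(m[["sensitivity"]], 1.0)
  expect_equal(m[["specificity"]], 0.75)
  expect_equal(m[["accuracy"]], 5 / 6, tolerance = 1e-12)
  expect_equal(m[["mcc"]], 6 / sqrt(72), tolerance = 1e-12)

  perfect <- binary_metrics(c(TP = 4, TN = 6, FP = 0, FN = 0))
  expect_equal(unname(perfect), rep(1, 4))
  # zero-denominator convention: no positives present
  none <- binary_metrics(c(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_equal(none[["sensitivity"]], 0)
  expect_equal(none[["mcc"]], 0)
  expect_error(binary_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("ROC/AUC behave under symmetry and degeneracy", {
  set.seed(8)
  truth <- rbinom(60, 1, 0.4) == 1
  scores <- ifelse(truth, rnorm(60, 1), rnorm(60))
  roc <- roc_curve(truth, scores)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
  flipped <- roc_curve(truth, 1 - scores)
  expect_equal(roc$auc + flipped$auc, 1, tolerance = 1e-12)
  # degenerate uniform scores: the diagonal
  expect_equal(roc_curve(truth, rep(1 / 3, 60))$auc, 0.5)
})

test_that("evaluate_predictions aggregates per-class and macro metrics", {
  y <- rep(RCCC_CLASSES, times = c(4, 3, 3))
  scores <- matrix(0, 10, 3)
  scores[cbind(1:10, match(y, RCCC_CLASSES))] <- 1
  rep_perfect <- evaluate_predictions(y, y, scores = scores)
  expect_equal(rep_perfect$macro$accuracy, 1)
  expect_equal(rep_perfect$macro$mcc, 1)
  for (cl in RCCC_CLASSES) expect_equal(rep_perfect$roc[[cl]]$auc, 1)

  # macro metrics are invariant to consistent class renaming
  y_pred <- c(y[2:10], y[1])
  swap <- c(kidney_tumor_driver = "unknown",
            other_tumor_driver = "kidney_tumor_driver",
            unknown = "other_tumor_driver")
  r1 <- evaluate_predictions(y, y_pred)
  r2 <- evaluate_predictions(unname(swap[y]), unname(swap[y_pred]))
  expect_equal(r1$macro, r2$macro)
})

test_that("reports serialize to JSON and round-trip losslessly", {
  feats <- small_sep_features(n_per_class = 8)
  report <- self_consistency(feats, train_config("decision_tree"))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(report, path)
  back <- read_report(path)
  expect_equal(back$macro$accuracy, report$macro$accuracy, tolerance = 1e-15)
  expect_equal(unlist(back$per_class), unlist(report$per_class),
               tolerance = 1e-15)
  expect_equal(unlist(back$roc$unknown), unlist(report$roc$unknown),
               tolerance = 1e-15)
  summ <- report_summary(report)
  expect_equal(summ$class, c(RCCC_CLASSES, "macro"))
  expect_equal(names(summ)[-1],
               c("Specificity", "Sensitivity", "Accuracy", "MCC"))
})

test_that("self-consistency handles degenerate datasets honestly", {
  base <- small_sep_features(n_per_class = 4)
  # two identical feature rows with conflicting labels cannot both be right
  conf <- base
  conf[2, c("M1", "M2", "M3", "M4", "Min", "Max")] <-
    conf[1, c("M1", "M2", "M3", "M4", "Min", "Max")]
  conf$label[1] <- "kidney_tumor_driver"
  conf$label[2] <- "unknown"
  rep_conf <- self_consistency(conf, train_config("decision_tree"))
  expect_lt(rep_conf$macro$accuracy, 1)
})

test_that("k-fold machinery partitions samples correctly", {
  feats <- random_features(37, seed = 21)
  ids <- rcccpred:::.fold_ids(feats$label, 5, seed = 2)
  expect_setequal(unique(ids), 1:5)
  for (cl in RCCC_CLASSES) {
    sizes <- table(ids[feats$label == cl])
    if (length(sizes) > 1) expect_lte(diff(range(sizes)), 1)
  }
  cv <- kfold_cv(feats, k = 5, config = train_config("naive_bayes"), seed = 2)
  expect_length(cv$per_fold_accuracy, 5)
  expect_equal(cv$n, 37)
  expect_length(cv$y_pred, 37)
  expect_false(anyNA(cv$y_pred))
  expect_error(kfold_cv(feats, k = 1), "k must be")
  expect_error(kfold_cv(feats, k = 100), "exceeds")
})

test_that("jackknife equals k-fold CV with k = n", {
  for (seed in 1:3) {
    feats <- random_features(20, seed = seed)
    cfg <- train_config("decision_tree")
    jk <- jackknife(feats, cfg)
    cv <- kfold_cv(feats, k = 20, config = cfg, seed = seed + 7)
    expect_identical(jk$y_pred, cv$y_pred)
    expect_equal(jk$macro, cv$macro)
  }
  tiny <- random_features(3, seed = 1)
  tiny$label <- RCCC_CLASSES
  expect_error(jackknife(tiny[1:2, ]), "at least 3")
  # 3 samples, one per class: runs and returns 3 pooled predictions
  jk3 <- jackknife(tiny, train_config("naive_bayes"))
  expect_length(jk3$y_pred, 3)
})

test_that("independent test evaluates only the held-out 30%", {
  feats <- small_sep_features(n_per_class = 10)
  rep_ind <- independent_test(feats, 0.7, train_config("decision_tree"),
                              seed = 5)
  expect_equal(rep_ind$n, 9)       # 30% of 30, stratified
  expect_equal(rep_ind$n_train, 21)
})

test_that("mean ROC over folds lives on the fixed 101-point grid", {
  feats <- small_sep_features(n_per_class = 10)
  cv <- kfold_cv(feats, k = 5, config = train_config("naive_bayes"), seed = 3)
  mr <- cv$mean_roc$kidney_tumor_driver
  expect_length(mr$fpr, 101)
  expect_equal(mr$fpr, seq(0, 1, length.out = 101))
  expect_true(all(mr$tpr >= 0 & mr$tpr <= 1))
  expect_gte(mr$auc, 0); expect_lte(mr$auc, 1)
})
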