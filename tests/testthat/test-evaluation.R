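test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusion_matrix(c("ST", "SI", "WA", "WA"), c("ST", "WA", "WA", "SI"))
  expect_equal(unclass(cm)[, ],
               matrix(c(1, 0, 0, 0, 0, 1, 0, 1, 1), 3, byrow = TRUE,
                      dimnames = list(true = c("ST", "SI", "WA"),
                                      predicted = c("ST", "SI", "WA"))))
  # perfect predictions: diagonal with trace n
  labs <- rep(c("ST", "SI", "WA"), c(3, 4, 3))
  perfect <- confusion_matrix(labs, labs)
  expect_equal(sum(diag(perfect)), 10)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  # everything predicted walking: only the WA column is populated
  allwa <- confusion_matrix(labs, rep("WA", 10))
  expect_true(all(allwa[, c("ST", "SI")] == 0))
  expect_equal(sum(allwa[, "WA"]), 10)
  # contract violations
  expect_error(confusion_matrix(c("ST", "XX"), c("ST", "SI")), "unknown")
  expect_error(confusion_matrix(c("ST"), c("ST", "SI")), "equal length")
})

test_that("accuracy is 100 * trace / total at 2 decimals", {
  expect_equal(accuracy_from_cm(diag(5)), 100)
  cm <- as_confusion_matrix(matrix(c(8, 2, 2, 8), 2, byrow = TRUE),
                            classes = c("ST", "SI"))
  expect_equal(accuracy_from_cm(cm), 80)
  expect_error(accuracy_from_cm(matrix(0, 2, 2)), "empty")
})

test_that("precision/recall/f1 match hand arithmetic on a symmetric toy", {
  cm <- as_confusion_matrix(matrix(c(8, 2, 2, 8), 2, byrow = TRUE),
                            classes = c("ST", "SI"))
  rep_ <- precision_recall_f1(cm)
  expect_equal(rep_$per_class$precision, c(80, 80))
  expect_equal(rep_$per_class$recall, c(80, 80))
  expect_equal(rep_$per_class$f1, c(80, 80))
  expect_equal(rep_$macro$f1, 80)
  expect_equal(rep_$accuracy, 80)
  # identity: all metrics 100
  ident <- precision_recall_f1(as_confusion_matrix(diag(3) * 5))
  expect_true(all(ident$per_class$precision == 100))
  expect_true(all(ident$per_class$f1 == 100))
})

test_that("never-predicted classes get zero metrics with an explicit flag", {
  # everything predicted walking (degenerate collapse)
  cm <- reference_cms("own100_OR")[["0.01"]]
  rep_ <- precision_recall_f1(cm)
  expect_equal(rep_$per_class$recall[rep_$per_class$class == "WA"], 100)
  expect_equal(rep_$per_class$recall[rep_$per_class$class %in% c("ST", "SI")],
               c(0, 0))
  expect_equal(rep_$per_class$precision[1:2], c(0, 0))
  expect_true(all(rep_$per_class$undefined_precision[1:2]))
  expect_false(rep_$per_class$undefined_precision[3])
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(31)
  classes <- c("ST", "SI", "WA")
  for (rep_i in 1:5) {
    truth <- factor(sample(classes, 300, TRUE), levels = classes)
    pred <- factor(sample(classes, 300, TRUE), levels = classes)
    cm <- confusion_matrix(as.character(truth), as.character(pred))
    ours <- precision_recall_f1(cm)
    ref <- caret::confusionMatrix(pred, truth)
    expect_lt(abs(ours$accuracy / 100 - unname(ref$overall["Accuracy"])), 1e-9)
    expect_lt(max(abs(ours$per_class$precision / 100 -
                        unname(ref$byClass[, "Precision"]))), 1e-9)
    expect_lt(max(abs(ours$per_class$recall / 100 -
                        unname(ref$byClass[, "Recall"]))), 1e-9)
    expect_lt(max(abs(ours$per_class$f1 / 100 -
                        unname(ref$byClass[, "F1"]))), 1e-9)
  }
})

test_that("accuracy deltas are full-precision differences, then rounded", {
  cm <- reference_cms("own200_OR")[["0.003"]]
  expect_equal(accuracy_delta(cm, cm), 0)
  a <- as_confusion_matrix(matrix(c(9, 1, 1, 9), 2, byrow = TRUE))
  b <- as_confusion_matrix(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(accuracy_delta(a, b), 40)
})

test_that("sweep evaluates every variant on one fixed test set", {
  fs <- separable_feature_set(n = 16)
  test_set <- separable_feature_set(n = 6, seed = 9)
  cfg <- lstm_config(hidden_units = 4, stacked_layers = 1, steps = 4,
                     max_epochs = 40, feature_transform = "none", seed = 1)
  res <- sweep_learning_rates(list(OR = fs), test_set,
                              learning_rates = 0.01, cfg = cfg)
  expect_equal(nrow(res$report), 1)
  expect_equal(res$report$n_test, 12)
  key <- names(res$matrices)[1]
  expect_equal(res$report$accuracy[1],
               accuracy_from_cm(res$matrices[[key]]))

  # two variants share the identical held-out rows
  aug <- augment_or_la1(fs, augmentation_spec(G1 = 4, shuffle_seed = 1))
  res2 <- sweep_learning_rates(list(OR = fs, `OR+LA1` = aug), test_set,
                               learning_rates = 0.01, cfg = cfg)
  expect_equal(unique(res2$report$n_test), 12)
  expect_true(all(vapply(res2$matrices, sum, numeric(1)) == 12))
  expect_error(sweep_learning_rates(list(fs), test_set, 0.01, cfg), "named")
})
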