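test_that("confusion matrices count truth rows against prediction columns", {
  cm <- confusion(c("AD", "AD", "HC"), c("AD", "HC", "HC"),
                  c("AD", "HC"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = dimnames(cm)),
               ignore_attr = TRUE)
  perfect <- confusion(rep(c("A", "B"), 5), rep(c("A", "B"), 5))
  expect_true(all(unclass(perfect)[upper.tri(perfect) |
                                     lower.tri(perfect)] == 0))
  set.seed(1)
  tr <- sample(c("A", "B", "C"), 60, TRUE)
  pr <- sample(c("A", "B", "C"), 60, TRUE)
  cm2 <- confusion(tr, pr)
  expect_equal(rowSums(cm2), table(factor(tr))[rownames(cm2)],
               ignore_attr = TRUE)
  expect_error(confusion("A", "D", class_order = c("A", "B")),
               "not in class_order")
})

test_that("metrics match a brute-force counting oracle", {
  set.seed(42)
  classes <- c("AD", "FTD", "HC")
  for (trial in 1:100) {
    n <- sample(5:40, 1)
    tr <- sample(classes, n, TRUE)
    pr <- sample(classes, n, TRUE)
    mr <- suppressWarnings(
      metrics_from_confusion(confusion(tr, pr, classes))
    )
    or <- oracle_metrics(tr, pr, classes)
    expect_equal(mr$accuracy, or$accuracy)
    expect_equal(mr$per_class$precision, or$per_class$precision)
    expect_equal(mr$per_class$recall, or$per_class$recall)
    expect_equal(mr$per_class$f1, or$per_class$f1)
    expect_equal(mr$per_class$specificity, or$per_class$specificity)
    expect_equal(mr$per_class$support, or$per_class$support)
  }
})

test_that("metric conventions: perfection, zero divisions, symmetry", {
  diag_cm <- as_confusion(diag(c(5L, 7L, 3L)), c("A", "B", "C"))
  mr <- metrics_from_confusion(diag_cm)
  expect_equal(mr$accuracy, 1)
  expect_true(all(mr$per_class$precision == 1))
  expect_true(all(mr$per_class$f1 == 1))

  # a class never predicted: precision 0 with a warning
  cm0 <- as_confusion(matrix(c(3L, 2L, 0L, 0L), 2), c("A", "B"))
  expect_warning(mr0 <- metrics_from_confusion(cm0), "precision")
  expect_equal(mr0$per_class$precision[2], 0)

  # binary complementarity: recall of A equals specificity of B
  cmb <- as_confusion(matrix(c(40L, 6L, 10L, 44L), 2), c("A", "B"))
  mrb <- metrics_from_confusion(cmb)
  expect_equal(mrb$per_class$recall[1], mrb$per_class$specificity[2])
  expect_equal(mrb$per_class$recall[2], mrb$per_class$specificity[1])

  # accuracy invariant under simultaneous class reordering
  cm3 <- as_confusion(matrix(c(8L, 1L, 2L, 0L, 7L, 1L, 1L, 2L, 9L), 3),
                      c("A", "B", "C"))
  perm <- c(3, 1, 2)
  cm3p <- as_confusion(unclass(cm3)[perm, perm], c("C", "A", "B"))
  expect_equal(metrics_from_confusion(cm3)$accuracy,
               metrics_from_confusion(cm3p)$accuracy)

  expect_error(metrics_from_confusion(as_confusion(matrix(0L, 2, 2))),
               "empty")
})

test_that("AUC matches the rank-sum oracle and its invariances", {
  # perfectly separated
  probs <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  colnames(probs) <- c("P", "N")
  r <- roc_auc(c("P", "P", "N", "N"), probs)
  expect_equal(unname(r$auc["P"]), 1)

  set.seed(33)
  for (trial in 1:20) {
    n <- sample(8:25, 1)
    truth <- sample(c("A", "B"), n, TRUE)
    if (length(unique(truth)) < 2) next
    # coarse scores so ties occur
    s <- round(runif(n), 1)
    probs2 <- cbind(A = s, B = 1 - s)
    r2 <- roc_auc(truth, probs2)
    expect_equal(unname(r2$auc["A"]), oracle_auc(s, truth == "A"))
  }

  # invariant under strictly monotone transforms of the scores
  set.seed(9)
  truth <- sample(c("A", "B"), 40, TRUE)
  s <- runif(40)
  a1 <- roc_auc(truth, cbind(A = s, B = 1 - s))$auc["A"]
  a2 <- roc_auc(truth, cbind(A = exp(3 * s), B = 1 - s))$auc["A"]
  expect_equal(a1, a2)

  # labels independent of scores: AUC near 1/2
  set.seed(100)
  truth3 <- sample(c("A", "B"), 4000, TRUE)
  s3 <- runif(4000)
  expect_equal(unname(roc_auc(truth3, cbind(A = s3, B = 1 - s3))$auc["A"]),
               0.5, tolerance = 0.05)

  # class absent from truth reported as missing
  r4 <- roc_auc(c("A", "A"), cbind(A = c(0.6, 0.7), B = c(0.4, 0.3)))
  expect_true(is.na(r4$auc["B"]))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  truth <- sample(c("A", "B"), 60, TRUE)
  s <- runif(60)
  ours <- unname(roc_auc(truth, cbind(A = s, B = 1 - s))$auc["A"])
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = truth == "A", predictor = s, quiet = TRUE,
    direction = "<"
  )))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("cross-validation trains per fold and reports k rows", {
  sep <- separable_features(n_per_class = 110, seed = 12)
  fm <- rbp_features(sep$x, colnames(sep$x),
                     ifelse(sep$y == "A", "AD", "HC"))
  rep2 <- crossval_report(
    fm, task = 3, k = 2,
    control = train_control(max_epochs = 80, seed = 5, val_frac = 0)
  )
  expect_equal(nrow(rep2), 2)
  expect_true(all(rep2$test_acc >= 0.95))
  expect_true(all(c("fold", "train_acc", "test_acc") %in% names(rep2)))
  expect_false(is.na(attr(rep2, "mean")))
})
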