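test_that("label encoding follows the four task definitions", {
  e1 <- encode_labels(c("AD", "FTD", "HC"), task = 1)
  expect_identical(e1$class_order, c("AD", "FTD", "HC"))
  expect_equal(e1$onehot[1, ], c(AD = 1L, FTD = 0L, HC = 0L))
  expect_true(all(rowSums(e1$onehot) == 1))

  e2 <- encode_labels(c("AD", "FTD", "HC"), task = 2)
  expect_identical(e2$class_order, c("Dementia", "HC"))
  expect_equal(e2$onehot[1, ], e2$onehot[2, ]) # AD and FTD merge

  e3 <- encode_labels(c("AD", "HC"), task = 3)
  expect_identical(e3$class_order, c("AD", "HC"))
  expect_error(encode_labels(c("AD", "FTD"), task = 3), "not part of task")
  expect_error(encode_labels(c("AD", "HC"), task = 4), "not part of task")
  expect_error(encode_labels("XX", task = 1), "unknown label")
  expect_error(encode_labels("AD", task = 7), "must be 1, 2, 3 or 4")
})

test_that("subset_task filters rows outside a binary task", {
  fm <- random_features(60, c("AD", "FTD", "HC"), seed = 3)
  t4 <- subset_task(fm, 4)
  expect_setequal(unique(t4$labels), c("FTD", "HC"))
  expect_equal(nrow(t4$values), sum(fm$labels != "AD"))
})

test_that("min-max normalization maps, inverts and degrades gracefully", {
  x <- matrix(c(0.2, 0.4, 0.6), 3, 1)
  mm <- fit_minmax(x)
  expect_equal(as.vector(apply_minmax(x, mm)), c(0, 0.5, 1))
  expect_equal(as.vector(apply_minmax(matrix(mm$min, 1), mm)), 0)

  set.seed(1)
  y <- matrix(runif(40), 10, 4)
  mm2 <- fit_minmax(y)
  z <- apply_minmax(y, mm2)
  back <- sweep(sweep(z, 2, mm2$max - mm2$min, "*"), 2, mm2$min, "+")
  expect_equal(back, y, tolerance = 1e-12)

  cns <- cbind(y[, 1], rep(0.5, 10))
  mm3 <- fit_minmax(cns)
  expect_warning(out <- apply_minmax(cns, mm3), "constant")
  expect_true(all(out[, 2] == 0))

  # order-preserving and affine per feature
  expect_identical(order(z[, 2]), order(y[, 2]))
})

test_that("splitting is exact, seeded, stratified and subject-aware", {
  fm <- random_features(100, c("AD", "HC"), seed = 5)
  sp <- split_features(fm, 0.8, 0.1, 0.1, seed = 2)
  expect_equal(nrow(sp$train$values), 80)
  expect_equal(nrow(sp$val$values), 10)
  expect_equal(nrow(sp$test$values), 10)
  idx <- attr(sp, "indices")
  expect_identical(sort(unname(unlist(idx))), 1:100)

  sp2 <- split_features(fm, 0.8, 0.1, 0.1, seed = 2)
  expect_identical(attr(sp2, "indices"), idx)

  # stratification keeps class shares close in the training partition
  tab_all <- table(fm$labels) / 100
  tab_tr <- table(sp$train$labels) / 80
  expect_lt(max(abs(tab_all - tab_tr)), 0.02)

  sps <- split_features(fm, 0.6, 0.2, 0.2, seed = 3, mode = "subject")
  parts <- list(sps$train$subject_ids, sps$val$subject_ids,
                sps$test$subject_ids)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_length(intersect(parts[[i]], parts[[j]]), 0)
  }

  expect_error(split_features(fm, 0.8, 0.1, 0.2), "sum to 1")
})

test_that("SMOTE grows minorities to the majority with convex samples", {
  fm <- random_features(120, "AD", seed = 8)
  fm$labels <- rep(c("AD", "FTD", "HC"), times = c(50, 40, 30))
  out <- smote_balance(fm, k_neighbors = 5, seed = 4)
  expect_equal(unname(table(out$labels)), rep(50L, 3), ignore_attr = TRUE)
  # originals preserved, first, unchanged
  expect_equal(out$values[1:120, ], fm$values)
  expect_identical(out$labels[1:120], fm$labels)
  # synthetic rows stay inside their class's bounding box
  for (cl in c("FTD", "HC")) {
    orig <- fm$values[fm$labels == cl, , drop = FALSE]
    synth <- out$values[-(1:120), , drop = FALSE][
      out$labels[-(1:120)] == cl, , drop = FALSE]
    expect_true(all(sweep(synth, 2, apply(orig, 2, max)) <= 1e-12))
    expect_true(all(sweep(synth, 2, apply(orig, 2, min)) >= -1e-12))
  }

  balanced <- random_features(60, "x", seed = 1)
  balanced$labels <- rep(c("A", "B"), 30)
  expect_identical(smote_balance(balanced), balanced)

  tiny <- random_features(24, "x", seed = 2)
  tiny$labels <- c(rep("A", 20), rep("B", 4))
  expect_error(smote_balance(tiny, k_neighbors = 5), "needs more than")
})

test_that("k-fold partitions are disjoint, exhaustive and stratified", {
  fm <- random_features(100, c("AD", "FTD", "HC"), seed = 9)
  folds <- kfold_partition(fm, k = 5, seed = 3)
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:100)
  sizes <- lengths(tests)
  expect_lte(max(sizes) - min(sizes), 1L)
  for (f in folds) {
    expect_identical(sort(c(f$train, f$test)), 1:100)
    # class proportions preserved within one row
    for (cl in unique(fm$labels)) {
      n_cl <- sum(fm$labels == cl)
      in_fold <- sum(fm$labels[f$test] == cl)
      expect_lte(abs(in_fold - n_cl / 5), 1)
    }
  }
  expect_error(kfold_partition(fm, k = 1), ">= 2")
  expect_error(kfold_partition(fm, k = 200), "exceeds")
})
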