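test_that("a constant model receives zero attributions", {
  f <- function(m) matrix(c(0.3, 0.7), nrow(m), 2, byrow = TRUE,
                          dimnames = list(NULL, c("A", "B")))
  set.seed(1)
  x <- matrix(runif(18), 3, 6)
  bg <- matrix(runif(30), 5, 6)
  attr_ <- shap_values(f, x, bg)
  expect_lt(max(abs(attr_$values)), 1e-6)
  expect_equal(unname(attr_$base_values), c(0.3, 0.7))
})

test_that("linear models get their exact closed-form Shapley values", {
  w <- c(0.5, -1.2, 2, 0, 0.3)
  f <- function(m) cbind(score = as.vector(m %*% w) + 1)
  set.seed(2)
  x <- matrix(runif(20), 4, 5)
  bg <- matrix(runif(40), 8, 5)
  attr_ <- shap_values(f, x, bg)
  for (i in 1:4) {
    expected <- w * (x[i, ] - colMeans(bg))
    expect_equal(unname(attr_$values[i, , 1]), unname(expected),
                 tolerance = 1e-10)
  }
  # single informative feature: attribution proportional to x - E[x]
  f1 <- function(m) cbind(s = 2 * m[, 3])
  a1 <- shap_values(f1, x, bg)
  expect_equal(unname(a1$values[, 3, 1]), 2 * (x[, 3] - mean(bg[, 3])),
               tolerance = 1e-10)
  expect_lt(max(abs(a1$values[, -3, 1])), 1e-12)
})

test_that("local accuracy holds exactly for the fitted classifier", {
  sep <- separable_features(n_per_class = 60, seed = 3)
  fit <- tcn_lstm(sep$x, sep$y,
                  control = train_control(max_epochs = 8, seed = 1,
                                          val_frac = 0))
  set.seed(4)
  x <- sep$x[sample(120, 50), ]
  bg <- shap_background(sep$x, n = 12, seed = 2)
  attr_ <- shap_values(fit, x, bg)
  preds <- predict(fit, x)
  recon <- sweep(apply(attr_$values, c(1, 3), sum), 2,
                 attr_$base_values, "+")
  expect_equal(unname(recon), unname(preds), tolerance = 1e-10)
})

test_that("duplicated features share their attribution symmetrically", {
  f <- function(m) cbind(s = m[, 1] + m[, 2])
  set.seed(5)
  x <- matrix(runif(8), 4, 2)
  x[, 2] <- x[, 1] # identical columns
  bg <- matrix(runif(12), 6, 2)
  bg[, 2] <- bg[, 1]
  attr_ <- shap_values(f, x, bg)
  expect_equal(attr_$values[, 1, 1], attr_$values[, 2, 1],
               tolerance = 1e-10)
})

test_that("importance ranking recovers the only informative feature", {
  f <- function(m) {
    z <- 6 * (m[, 5] - 0.5)
    p <- 1 / (1 + exp(-z))
    cbind(A = 1 - p, B = p)
  }
  set.seed(6)
  x <- matrix(runif(120), 20, 6)
  colnames(x) <- band_scheme("modified")$band
  bg <- matrix(runif(60), 10, 6)
  attr_ <- shap_values(f, x, bg, feature_names = colnames(x))
  for (cl in c("A", "B")) {
    gi <- global_importance(attr_, cl)
    expect_identical(gi$feature[1], "Beta")
  }
  expect_error(global_importance(attr_, "Z"), "unknown class")
})

test_that("summary and heatmap exports are consistent with importance", {
  f <- function(m) cbind(s = as.vector(m %*% c(1, -1, 0.5)))
  set.seed(7)
  x <- matrix(runif(24), 8, 3)
  bg <- matrix(runif(15), 5, 3)
  attr_ <- shap_values(f, x, bg, feature_names = c("a", "b", "c"))
  hd <- heatmap_data(attr_, "s")
  expect_equal(nrow(hd$matrix), 8)
  gi <- global_importance(attr_, "s")
  expect_equal(sort(unname(hd$importance), decreasing = TRUE),
               gi$importance)
  sd_ <- summary_data(attr_, "s")
  expect_equal(nrow(sd_), 8 * 3)
  # summary table round-trips through CSV at full precision
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sd_, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$shap_value, sd_$shap_value, tolerance = 1e-10)

  expect_error(shap_values(f, x, matrix(numeric(0), 0, 3)),
               "empty background")
})
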