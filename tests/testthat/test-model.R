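test_that("the parameter census scales with the architecture", {
  cp5 <- count_params(model_spec(input_len = 5, n_classes = 2))
  # changing the input length leaves counts unchanged; the head shrinks
  cp6 <- count_params(model_spec(input_len = 6, n_classes = 3))
  expect_equal(cp6$total - cp5$total, 771 - (256 * 2 + 2))
  expect_equal(cp5$non_trainable, 256)
  # census equals the size of the actual parameter store
  spec <- model_spec(input_len = 6, n_classes = 3)
  params <- eegdem:::init_params(spec, seed = 1)
  expect_equal(sum(lengths(params)), count_params(spec)$total)
  frozen <- eegdem:::nontrainable_names(params)
  expect_equal(sum(lengths(params[frozen])),
               count_params(spec)$non_trainable)
})

test_that("untrained model emits simplex rows, deterministically", {
  set.seed(2)
  fit <- tcn_lstm(matrix(runif(60), 10, 6), rep(c("A", "B"), 5),
                  control = train_control(max_epochs = 0))
  x <- matrix(runif(30), 5, 6)
  p1 <- predict(fit, x)
  p2 <- predict(fit, x)
  expect_equal(rowSums(p1), rep(1, 5), tolerance = 1e-6)
  expect_identical(p1, p2) # dropout inactive at inference
  expect_identical(colnames(p1), c("A", "B"))
  cls <- predict(fit, x, type = "class")
  expect_identical(cls, c("A", "B")[max.col(p1)])
  # permuting rows permutes predictions
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predict(fit, x[perm, ]), p1[perm, ])
  expect_error(predict(fit, x[, 1:4]), "does not match")
  expect_equal(nrow(fit$history), 0)
})

test_that("tcn block: zero weights give the projected residual only", {
  set.seed(6)
  k <- 7
  f <- 3
  w <- list(
    conv1_w = array(0, c(k, 1, f)), conv1_b = numeric(f),
    conv2_w = array(0, c(k, f, f)), conv2_b = numeric(f),
    proj_w = array(rnorm(f), c(1, 1, f)), proj_b = rnorm(f)
  )
  x <- matrix(rnorm(6), 6, 1)
  out <- tcn_block_forward(x, w)
  proj <- eegdem:::conv1d_forward(
    array(x, c(1, 6, 1)), w$proj_w, w$proj_b
  )
  expect_equal(out, matrix(proj, 6, f))
})

test_that("tcn block: identity kernel on the linear path reproduces x", {
  f <- 2
  k <- 3
  ident <- array(0, c(k, f, f))
  ident[1, , ] <- diag(f)
  w <- list(
    conv1_w = ident, conv1_b = numeric(f),
    conv2_w = ident, conv2_b = numeric(f),
    proj_w = array(0, c(1, f, f)), proj_b = numeric(f)
  )
  x <- matrix(rnorm(12), 6, f)
  out <- tcn_block_forward(x, w, activation = "linear", use_bn = FALSE)
  expect_equal(out, x)
})

test_that("block output is causal: perturbations propagate forward only", {
  set.seed(11)
  spec <- model_spec(input_len = 6, n_classes = 3)
  params <- eegdem:::init_params(spec, seed = 5)
  w <- stats::setNames(
    params[grep("^block1_", names(params))],
    sub("^block1_", "", grep("^block1_", names(params), value = TRUE))
  )
  x <- matrix(rnorm(6), 6, 1)
  base <- tcn_block_forward(x, w)
  for (t in 1:6) {
    xp <- x
    xp[t, 1] <- xp[t, 1] + 0.37
    out <- tcn_block_forward(xp, w)
    changed <- rowSums(abs(out - base)) > 1e-12
    if (t > 1) expect_false(any(changed[1:(t - 1)]))
    expect_true(changed[t])
  }
})

test_that("analytic gradients match finite differences", {
  spec <- model_spec(
    input_len = 4, n_classes = 2, filters = 3, kernel_size = 2,
    lstm_units = 4, dense_units = c(5, 4), spatial_dropout = 0,
    dense_dropout = 0
  )
  params <- eegdem:::init_params(spec, seed = 7)
  set.seed(99)
  # move off the zero-bias ReLU kinks so finite differences are valid
  for (nm in names(params)) {
    params[[nm]][] <- params[[nm]] + rnorm(length(params[[nm]]), sd = 0.05)
  }
  x <- array(rnorm(6 * 4), c(6, 4, 1))
  y <- matrix(0, 6, 2)
  y[cbind(1:6, sample(1:2, 6, TRUE))] <- 1
  lossfun <- function(p) {
    fw <- eegdem:::nn_forward(p, spec, x, training = TRUE)
    eegdem:::softmax_crossentropy(fw$logits, y)$loss
  }
  fw <- eegdem:::nn_forward(params, spec, x, training = TRUE)
  ce <- eegdem:::softmax_crossentropy(fw$logits, y)
  g <- eegdem:::nn_backward(ce$dlogits, params, spec, fw$cache)
  eps <- 1e-5
  for (nm in names(g)) {
    pv <- params[[nm]]
    idx <- unique(round(seq(1, length(pv), length.out = min(4, length(pv)))))
    for (ii in idx) {
      p2 <- params
      p2[[nm]][ii] <- p2[[nm]][ii] + eps
      p3 <- params
      p3[[nm]][ii] <- p3[[nm]][ii] - eps
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      expect_equal(g[[nm]][ii], num, tolerance = 1e-3,
                   label = paste("grad", nm))
    }
  }
})

test_that("one-batch training drives the loss down monotonically", {
  set.seed(14)
  x <- matrix(runif(32 * 6), 32, 6)
  y <- rep(c("A", "B"), 16)
  # dropout off so the per-epoch loss is a deterministic function of the
  # weights and its decrease is a clean optimizer check
  fit <- tcn_lstm(
    x, y,
    spec = model_spec(input_len = 6, n_classes = 2,
                      spatial_dropout = 0, dense_dropout = 0),
    control = train_control(max_epochs = 5, val_frac = 0, seed = 2)
  )
  expect_equal(nrow(fit$history), 5)
  expect_true(all(diff(fit$history$loss) < 0))
})

test_that("the classifier separates two classes split on one band", {
  sep <- separable_features(n_per_class = 120, seed = 31)
  hold <- c(1:20, 121:140)
  fit <- tcn_lstm(
    sep$x[-hold, ], sep$y[-hold],
    control = train_control(max_epochs = 40, seed = 7)
  )
  acc <- mean(predict(fit, sep$x[hold, ], type = "class") == sep$y[hold])
  expect_gte(acc, 0.95)
  expect_lt(nrow(fit$history), 41) # history recorded per epoch
})

test_that("class mismatches are caught before training", {
  x <- matrix(runif(30), 5, 6)
  expect_error(
    tcn_lstm(x, c("A", "B", "C", "A", "B"),
             spec = model_spec(input_len = 6, n_classes = 2)),
    "does not match"
  )
  expect_error(tcn_lstm(x, c("A", "B")), "nrow")
})
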