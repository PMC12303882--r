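# The hybrid TCN-LSTM classifier: two residual causal-convolution blocks
# (32 filters, kernel 7, kernel-1 residual projections, batch
# normalization, spatial dropout) feeding a 64-unit LSTM and a 128/192/256
# dense head with softmax output. Built, trained (Adam, categorical
# cross-entropy, early stopping) and differentiated entirely in R.

#' Architecture specification for the TCN-LSTM classifier
#'
#' Defaults reproduce the reference lightweight architecture: with
#' `input_len = 6` and `n_classes = 3` the parameter census is 131,587
#' total, 131,331 trainable and 256 non-trainable (the moving statistics
#' of the four batch-normalization layers).
#'
#' @param input_len length of the input sequence (number of band-power
#'   features; 6 for the modified scheme, 5 for the standard one).
#' @param n_classes number of output classes (2 or 3).
#' @param n_blocks number of residual convolution blocks.
#' @param filters convolution filters per layer.
#' @param kernel_size convolution kernel size (causal padding keeps the
#'   sequence length).
#' @param dilation dilation rate of the causal convolutions.
#' @param spatial_dropout channel-dropout rate inside the blocks.
#' @param lstm_units LSTM hidden units.
#' @param dense_units widths of the dense head.
#' @param dense_dropout dropout rate between dense layers.
#' @return Object of class `tcn_lstm_spec`.
#' @export
model_spec <- function(input_len = 6, n_classes = 3, n_blocks = 2,
                       filters = 32, kernel_size = 7, dilation = 1,
                       spatial_dropout = 0.2, lstm_units = 64,
                       dense_units = c(128, 192, 256),
                       dense_dropout = 0.2) {
  stopifnot(
    input_len >= 1, n_classes >= 2, n_blocks >= 1, filters >= 1,
    kernel_size >= 1, dilation >= 1, lstm_units >= 1,
    length(dense_units) >= 1, all(dense_units >= 1)
  )
  if (spatial_dropout < 0 || spatial_dropout >= 1 ||
      dense_dropout < 0 || dense_dropout >= 1) {
    stop("dropout rates must lie in [0, 1)")
  }
  structure(
    list(
      input_len = as.integer(input_len), n_classes = as.integer(n_classes),
      n_blocks = as.integer(n_blocks), filters = as.integer(filters),
      kernel_size = as.integer(kernel_size), dilation = as.integer(dilation),
      spatial_dropout = spatial_dropout,
      lstm_units = as.integer(lstm_units),
      dense_units = as.integer(dense_units), dense_dropout = dense_dropout
    ),
    class = "tcn_lstm_spec"
  )
}

block_in_channels <- function(spec, b) if (b == 1L) 1L else spec$filters

init_params <- function(spec, seed = 1) {
  set.seed(as.integer(seed))
  p <- list()
  f <- spec$filters
  k <- spec$kernel_size
  for (b in seq_len(spec$n_blocks)) {
    cin <- block_in_channels(spec, b)
    pre <- sprintf("block%d_", b)
    p[[paste0(pre, "conv1_w")]] <- glorot_uniform(c(k, cin, f), k * cin, k * f)
    p[[paste0(pre, "conv1_b")]] <- numeric(f)
    p[[paste0(pre, "bn1_gamma")]] <- rep(1, f)
    p[[paste0(pre, "bn1_beta")]] <- numeric(f)
    p[[paste0(pre, "bn1_mean")]] <- numeric(f)
    p[[paste0(pre, "bn1_var")]] <- rep(1, f)
    p[[paste0(pre, "conv2_w")]] <- glorot_uniform(c(k, f, f), k * f, k * f)
    p[[paste0(pre, "conv2_b")]] <- numeric(f)
    p[[paste0(pre, "bn2_gamma")]] <- rep(1, f)
    p[[paste0(pre, "bn2_beta")]] <- numeric(f)
    p[[paste0(pre, "bn2_mean")]] <- numeric(f)
    p[[paste0(pre, "bn2_var")]] <- rep(1, f)
    p[[paste0(pre, "proj_w")]] <- glorot_uniform(c(1L, cin, f), cin, f)
    p[[paste0(pre, "proj_b")]] <- numeric(f)
  }
  h <- spec$lstm_units
  p$lstm_wx <- glorot_uniform(c(f, 4L * h), f, 4L * h)
  wh <- matrix(0, h, 4L * h)
  for (g in 1:4) wh[, ((g - 1L) * h + 1L):(g * h)] <- orthogonal_init(h, h)
  p$lstm_wh <- wh
  bb <- numeric(4L * h)
  bb[(h + 1L):(2L * h)] <- 1 # unit forget-gate bias
  p$lstm_b <- bb
  prev <- h
  for (i in seq_along(spec$dense_units)) {
    u <- spec$dense_units[i]
    p[[sprintf("dense%d_w", i)]] <- glorot_uniform(c(prev, u), prev, u)
    p[[sprintf("dense%d_b", i)]] <- numeric(u)
    prev <- u
  }
  p$out_w <- glorot_uniform(c(prev, spec$n_classes), prev, spec$n_classes)
  p$out_b <- numeric(spec$n_classes)
  p
}

nontrainable_names <- function(params) {
  grep("_(mean|var)$", names(params), value = TRUE)
}

#' Parameter census of the architecture
#'
#' Counts parameters layer by layer the way a framework summary would:
#' batch-normalization layers contribute their scale/shift pairs as
#' trainable and their moving statistics as non-trainable.
#'
#' @param x a `tcn_lstm_spec` or a fitted `tcn_lstm` model.
#' @return List with `total`, `trainable`, `non_trainable` counts and a
#'   `layers` data frame (layer name, output shape, parameter count).
#' @export
count_params <- function(x) {
  spec <- if (inherits(x, "tcn_lstm")) x$spec else x
  stopifnot(inherits(spec, "tcn_lstm_spec"))
  f <- spec$filters
  k <- spec$kernel_size
  len <- spec$input_len
  seq_shape <- sprintf("(None, %d, %d)", len, f)
  rows <- list(list("input", sprintf("(None, %d, 1)", len), 0L, 0L))
  for (b in seq_len(spec$n_blocks)) {
    cin <- block_in_channels(spec, b)
    pre <- sprintf("block%d_", b)
    rows <- c(rows, list(
      list(paste0(pre, "conv1"), seq_shape, k * cin * f + f, 0L),
      list(paste0(pre, "bn1"), seq_shape, 4L * f, 2L * f),
      list(paste0(pre, "conv2"), seq_shape, k * f * f + f, 0L),
      list(paste0(pre, "bn2"), seq_shape, 4L * f, 2L * f),
      list(paste0(pre, "proj"), seq_shape, cin * f + f, 0L)
    ))
  }
  h <- spec$lstm_units
  rows <- c(rows, list(
    list("lstm", sprintf("(None, %d)", h), 4L * (h * (f + h) + h), 0L)
  ))
  prev <- h
  for (i in seq_along(spec$dense_units)) {
    u <- spec$dense_units[i]
    rows <- c(rows, list(
      list(sprintf("dense%d", i), sprintf("(None, %d)", u),
           prev * u + u, 0L)
    ))
    prev <- u
  }
  rows <- c(rows, list(
    list("output", sprintf("(None, %d)", spec$n_classes),
         prev * spec$n_classes + spec$n_classes, 0L)
  ))
  layers <- data.frame(
    layer = vapply(rows, `[[`, "", 1),
    output_shape = vapply(rows, `[[`, "", 2),
    params = vapply(rows, function(r) as.integer(r[[3]]), 0L),
    non_trainable = vapply(rows, function(r) as.integer(r[[4]]), 0L),
    stringsAsFactors = FALSE
  )
  total <- sum(layers$params)
  non_tr <- sum(layers$non_trainable)
  list(
    total = total, trainable = total - non_tr, non_trainable = non_tr,
    layers = layers
  )
}

# --- forward / backward ----------------------------------------------------

block_forward <- function(x, params, pre, spec, training,
                          bn_momentum = 0.9) {
  cache <- list(x = x)
  c1 <- conv1d_forward(x, params[[paste0(pre, "conv1_w")]],
                       params[[paste0(pre, "conv1_b")]])
  bn1 <- batchnorm_forward(
    c1, params[[paste0(pre, "bn1_gamma")]], params[[paste0(pre, "bn1_beta")]],
    params[[paste0(pre, "bn1_mean")]], params[[paste0(pre, "bn1_var")]],
    training, momentum = bn_momentum
  )
  a1 <- pmax(bn1$out, 0)
  sd1 <- spatial_dropout_forward(a1, spec$spatial_dropout, training)
  c2 <- conv1d_forward(sd1$out, params[[paste0(pre, "conv2_w")]],
                       params[[paste0(pre, "conv2_b")]])
  bn2 <- batchnorm_forward(
    c2, params[[paste0(pre, "bn2_gamma")]], params[[paste0(pre, "bn2_beta")]],
    params[[paste0(pre, "bn2_mean")]], params[[paste0(pre, "bn2_var")]],
    training, momentum = bn_momentum
  )
  a2 <- pmax(bn2$out, 0)
  sd2 <- spatial_dropout_forward(a2, spec$spatial_dropout, training)
  proj <- conv1d_forward(x, params[[paste0(pre, "proj_w")]],
                         params[[paste0(pre, "proj_b")]])
  cache$c1 <- c1; cache$bn1 <- bn1$cache; cache$a1 <- a1
  cache$sd1 <- sd1; cache$c2 <- c2; cache$bn2 <- bn2$cache
  cache$a2 <- a2; cache$sd2 <- sd2
  list(
    out = proj + sd2$out, cache = cache,
    rstats = stats::setNames(
      list(bn1$rmean, bn1$rvar, bn2$rmean, bn2$rvar),
      paste0(pre, c("bn1_mean", "bn1_var", "bn2_mean", "bn2_var"))
    )
  )
}

block_backward <- function(dout, cache, params, pre) {
  g <- list()
  # projection path
  pb <- conv1d_backward(dout, cache$x, params[[paste0(pre, "proj_w")]])
  g[[paste0(pre, "proj_w")]] <- pb$dw
  g[[paste0(pre, "proj_b")]] <- pb$db
  # main path
  da2 <- if (is.null(cache$sd2$mask)) dout else dout * cache$sd2$mask
  dbn2 <- da2 * (cache$a2 > 0)
  bb2 <- batchnorm_backward(dbn2, cache$bn2)
  g[[paste0(pre, "bn2_gamma")]] <- bb2$dgamma
  g[[paste0(pre, "bn2_beta")]] <- bb2$dbeta
  cb2 <- conv1d_backward(bb2$dx, cache$sd1$out,
                         params[[paste0(pre, "conv2_w")]])
  g[[paste0(pre, "conv2_w")]] <- cb2$dw
  g[[paste0(pre, "conv2_b")]] <- cb2$db
  da1 <- if (is.null(cache$sd1$mask)) cb2$dx else cb2$dx * cache$sd1$mask
  dbn1 <- da1 * (cache$a1 > 0)
  bb1 <- batchnorm_backward(dbn1, cache$bn1)
  g[[paste0(pre, "bn1_gamma")]] <- bb1$dgamma
  g[[paste0(pre, "bn1_beta")]] <- bb1$dbeta
  cb1 <- conv1d_backward(bb1$dx, cache$x,
                         params[[paste0(pre, "conv1_w")]])
  g[[paste0(pre, "conv1_w")]] <- cb1$dw
  g[[paste0(pre, "conv1_b")]] <- cb1$db
  list(dx = pb$dx + cb1$dx, grads = g)
}

nn_forward <- function(params, spec, x, training = FALSE,
                       bn_momentum = 0.9) {
  cache <- list(blocks = vector("list", spec$n_blocks))
  rstats <- list()
  h <- x
  for (b in seq_len(spec$n_blocks)) {
    bf <- block_forward(h, params, sprintf("block%d_", b), spec, training,
                        bn_momentum)
    cache$blocks[[b]] <- bf$cache
    rstats <- c(rstats, bf$rstats)
    h <- bf$out
  }
  lf <- lstm_forward(h, params$lstm_wx, params$lstm_wh, params$lstm_b)
  cache$lstm <- lf
  a <- lf$out
  cache$dense <- vector("list", length(spec$dense_units))
  for (i in seq_along(spec$dense_units)) {
    z <- dense_forward(a, params[[sprintf("dense%d_w", i)]],
                       params[[sprintf("dense%d_b", i)]])
    r <- pmax(z, 0)
    dr <- dropout_forward(r, spec$dense_dropout, training)
    cache$dense[[i]] <- list(a_in = a, z = z, relu = r, drop = dr)
    a <- dr$out
  }
  cache$head_in <- a
  logits <- dense_forward(a, params$out_w, params$out_b)
  list(logits = logits, probs = softmax(logits), cache = cache,
       rstats = rstats)
}

nn_backward <- function(dlogits, params, spec, cache) {
  g <- list()
  g$out_w <- crossprod(cache$head_in, dlogits)
  g$out_b <- colSums(dlogits)
  da <- dlogits %*% t(params$out_w)
  for (i in rev(seq_along(spec$dense_units))) {
    dc <- cache$dense[[i]]
    dr <- if (is.null(dc$drop$mask)) da else da * dc$drop$mask
    dz <- dr * (dc$z > 0)
    g[[sprintf("dense%d_w", i)]] <- crossprod(dc$a_in, dz)
    g[[sprintf("dense%d_b", i)]] <- colSums(dz)
    da <- dz %*% t(params[[sprintf("dense%d_w", i)]])
  }
  lb <- lstm_backward(da, cache$lstm, params$lstm_wx, params$lstm_wh)
  g$lstm_wx <- lb$dwx
  g$lstm_wh <- lb$dwh
  g$lstm_b <- lb$db
  dh <- lb$dx
  for (b in rev(seq_len(spec$n_blocks))) {
    bb <- block_backward(dh, cache$blocks[[b]], params,
                         sprintf("block%d_", b))
    g <- c(g, bb$grads)
    dh <- bb$dx
  }
  g
}

as_input_array <- function(x, input_len) {
  x <- as.matrix(x)
  if (ncol(x) != input_len) {
    stop("feature width ", ncol(x), " does not match the model input length ",
         input_len)
  }
  array(x, c(nrow(x), input_len, 1L))
}

#' Forward pass through one residual TCN block
#'
#' Exposes the block computation for inspection: causal convolution,
#' batch normalization, activation, spatial dropout, a second
#' convolution/normalization/activation/dropout, and the kernel-1
#' projection of the block input added as the residual. At inference
#' (`training = FALSE`) batch normalization uses its stored statistics and
#' dropout is inactive, so output at time `t` depends only on inputs at
#' times `<= t`.
#'
#' @param x input sequence: a `len x channels` matrix or a
#'   `(batch, len, channels)` array.
#' @param weights named list with `conv1_w`, `conv1_b`, `conv2_w`,
#'   `conv2_b`, `proj_w`, `proj_b` and optionally `bn1_*`/`bn2_*`
#'   (gamma/beta/mean/var; identity normalization is used when absent).
#' @param activation `"relu"` or `"linear"`.
#' @param use_bn apply batch normalization (default TRUE).
#' @param training use batch statistics and active dropout.
#' @param spatial_dropout dropout rate when `training = TRUE`.
#' @return Output sequence with the same shape as `x`.
#' @export
tcn_block_forward <- function(x, weights, activation = c("relu", "linear"),
                              use_bn = TRUE, training = FALSE,
                              spatial_dropout = 0) {
  activation <- match.arg(activation)
  squeeze <- FALSE
  if (is.matrix(x)) {
    x <- array(x, c(1L, nrow(x), ncol(x)))
    squeeze <- TRUE
  }
  f <- dim(weights$conv1_w)[3]
  wts <- weights
  if (use_bn) {
    for (bn in c("bn1", "bn2")) {
      if (is.null(wts[[paste0(bn, "_gamma")]])) {
        wts[[paste0(bn, "_gamma")]] <- rep(1, f)
        wts[[paste0(bn, "_beta")]] <- numeric(f)
        wts[[paste0(bn, "_mean")]] <- numeric(f)
        wts[[paste0(bn, "_var")]] <- rep(1, f)
      }
    }
  }
  act <- if (activation == "relu") function(z) pmax(z, 0) else identity
  run_bn <- function(z, bn) {
    if (!use_bn) return(z)
    batchnorm_forward(
      z, wts[[paste0(bn, "_gamma")]], wts[[paste0(bn, "_beta")]],
      wts[[paste0(bn, "_mean")]], wts[[paste0(bn, "_var")]], training
    )$out
  }
  a1 <- act(run_bn(conv1d_forward(x, wts$conv1_w, wts$conv1_b), "bn1"))
  a1 <- spatial_dropout_forward(a1, spatial_dropout, training)$out
  a2 <- act(run_bn(conv1d_forward(a1, wts$conv2_w, wts$conv2_b), "bn2"))
  a2 <- spatial_dropout_forward(a2, spatial_dropout, training)$out
  out <- conv1d_forward(x, wts$proj_w, wts$proj_b) + a2
  if (squeeze) matrix(out, dim(out)[2], dim(out)[3]) else out
}

#' Extract one block's weights from a fitted model
#' @param object a fitted `tcn_lstm` model.
#' @param block block index.
#' @return Named weight list suitable for [tcn_block_forward()].
#' @export
block_weights <- function(object, block = 1) {
  stopifnot(inherits(object, "tcn_lstm"))
  pre <- sprintf("block%d_", block)
  nms <- grep(paste0("^", pre), names(object$params), value = TRUE)
  stats::setNames(object$params[nms], sub(pre, "", nms))
}

#' Training control parameters
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs maximum training epochs (default 100; 0 returns the
#'   initialized model unchanged).
#' @param patience early-stopping patience in epochs, monitoring
#'   validation loss; the best-validation weights are restored.
#' @param val_frac fraction of the training data held out for validation
#'   when no explicit validation set is supplied.
#' @param bn_momentum momentum of the batch-normalization moving
#'   statistics. The default 0.9 suits the short-epoch regime of this
#'   feature matrix (a handful of minibatches per epoch), letting the
#'   inference statistics track the batch statistics within a few epochs.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return List of class `train_control`.
#' @export
train_control <- function(learning_rate = 1e-4, batch_size = 32,
                          max_epochs = 100, patience = 10, val_frac = 0.1,
                          bn_momentum = 0.9, seed = 1, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 0,
            patience >= 1, val_frac >= 0, val_frac < 1,
            bn_momentum >= 0, bn_momentum < 1)
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      val_frac = val_frac, bn_momentum = bn_momentum,
      seed = as.integer(seed), verbose = verbose
    ),
    class = "train_control"
  )
}

eval_dataset <- function(params, spec, x_arr, onehot) {
  fw <- nn_forward(params, spec, x_arr, training = FALSE)
  ce <- softmax_crossentropy(fw$logits, onehot)
  acc <- mean(max.col(fw$probs) == max.col(onehot))
  list(loss = ce$loss, acc = acc)
}

#' Fit the TCN-LSTM classifier
#'
#' Trains the hybrid temporal-convolution + LSTM network on a feature
#' matrix with the Adam optimizer and categorical cross-entropy, stopping
#' early when the validation loss fails to improve for `patience` epochs
#' and restoring the best-validation weights. All randomness
#' (initialization, shuffling, dropout) is governed by `control$seed`.
#'
#' @param x numeric matrix of features (rows = instances, columns in band
#'   order), already normalized.
#' @param y class labels (character or factor); the class order is the
#'   sorted set of unique labels.
#' @param spec a [model_spec()]; defaults to the reference architecture
#'   sized to `ncol(x)` and the number of classes in `y`.
#' @param control a [train_control()].
#' @param validation optional list with elements `x` and `y` used for
#'   early stopping; when absent, `control$val_frac` of the rows is held
#'   out (stratified).
#' @return Object of class `tcn_lstm` with elements `spec`, `params`,
#'   `class_order`, `history` (per-epoch loss/accuracy), `control` and
#'   `feature_names`. Methods: [predict.tcn_lstm()], `print`, `summary`,
#'   `plot`, `coef`.
#' @export
tcn_lstm <- function(x, y, spec = NULL, control = train_control(),
                     validation = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  class_order <- sort(unique(y))
  if (is.null(spec)) {
    spec <- model_spec(input_len = ncol(x),
                       n_classes = length(class_order))
  }
  if (spec$n_classes != length(class_order)) {
    stop("spec$n_classes (", spec$n_classes, ") does not match the ",
         length(class_order), " classes present in y")
  }
  set.seed(control$seed)
  params <- init_params(spec, seed = control$seed)

  onehot_of <- function(lab) {
    m <- matrix(0, length(lab), length(class_order),
                dimnames = list(NULL, class_order))
    m[cbind(seq_along(lab), match(lab, class_order))] <- 1
    m
  }

  if (is.null(validation) && control$val_frac > 0 &&
      control$max_epochs > 0) {
    val_idx <- integer(0)
    for (g in split(seq_len(nrow(x)), y)) {
      g <- g[sample.int(length(g))]
      n_v <- max(1L, round(control$val_frac * length(g)))
      val_idx <- c(val_idx, g[seq_len(n_v)])
    }
    validation <- list(x = x[val_idx, , drop = FALSE], y = y[val_idx])
    keep <- setdiff(seq_len(nrow(x)), val_idx)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }

  x_arr <- as_input_array(x, spec$input_len)
  y_hot <- onehot_of(y)
  has_val <- !is.null(validation)
  if (has_val) {
    vx <- as_input_array(as.matrix(validation$x), spec$input_len)
    vy <- onehot_of(as.character(validation$y))
  }

  history <- data.frame(
    epoch = integer(0), loss = numeric(0), acc = numeric(0),
    val_loss = numeric(0), val_acc = numeric(0)
  )
  opt <- adam_init(params)
  frozen <- nontrainable_names(params)
  best_loss <- Inf
  best_params <- params
  wait <- 0L
  n <- nrow(x)

  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    ep_loss <- 0
    ep_hits <- 0
    for (idx in batches) {
      xb <- x_arr[idx, , , drop = FALSE]
      yb <- y_hot[idx, , drop = FALSE]
      fw <- nn_forward(params, spec, xb, training = TRUE,
                       bn_momentum = control$bn_momentum)
      for (nm in names(fw$rstats)) params[[nm]] <- fw$rstats[[nm]]
      ce <- softmax_crossentropy(fw$logits, yb)
      if (!is.finite(ce$loss)) {
        stop(sprintf(
          "NaN/Inf loss at epoch %d (lr = %g): training diverged",
          epoch, control$learning_rate
        ))
      }
      grads <- nn_backward(ce$dlogits, params, spec, fw$cache)
      upd <- adam_step(params, grads, opt, lr = control$learning_rate,
                       skip = frozen)
      params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + ce$loss * length(idx)
      ep_hits <- ep_hits + sum(max.col(fw$probs) == max.col(yb))
    }
    val_loss <- NA_real_
    val_acc <- NA_real_
    if (has_val) {
      ev <- eval_dataset(params, spec, vx, vy)
      val_loss <- ev$loss
      val_acc <- ev$acc
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss / n, acc = ep_hits / n,
      val_loss = val_loss, val_acc = val_acc
    ))
    if (control$verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  acc %.3f  val_loss %s  val_acc %s",
        epoch, ep_loss / n, ep_hits / n,
        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))
      ))
    }
    if (has_val) {
      if (val_loss < best_loss - 1e-8) {
        best_loss <- val_loss
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
    }
  }
  if (has_val && control$max_epochs > 0) params <- best_params

  structure(
    list(
      spec = spec, params = params, class_order = class_order,
      history = history, control = control,
      feature_names = colnames(x), call = match.call()
    ),
    class = "tcn_lstm"
  )
}

#' Predict class probabilities or labels
#'
#' Dropout and batch-normalization batch statistics are inactive at
#' inference, so repeated calls on the same input are identical and each
#' probability row lies on the simplex.
#'
#' @param object a fitted `tcn_lstm` model.
#' @param newdata feature matrix with the model's input width.
#' @param type `"prob"` for the class-probability matrix, `"class"` for
#'   predicted labels.
#' @param ... unused.
#' @export
predict.tcn_lstm <- function(object, newdata,
                             type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "rbp_features")) newdata <- newdata$values
  x_arr <- as_input_array(newdata, object$spec$input_len)
  probs <- nn_forward(object$params, object$spec, x_arr,
                      training = FALSE)$probs
  colnames(probs) <- object$class_order
  if (type == "prob") probs else object$class_order[max.col(probs)]
}

#' @export
print.tcn_lstm <- function(x, ...) {
  cp <- count_params(x$spec)
  cat("TCN-LSTM classifier\n")
  cat(sprintf(
    "  input length %d, classes: %s\n",
    x$spec$input_len, paste(x$class_order, collapse = ", ")
  ))
  cat(sprintf(
    "  parameters: %s total (%s trainable, %s non-trainable)\n",
    format(cp$total, big.mark = ","),
    format(cp$trainable, big.mark = ","),
    format(cp$non_trainable, big.mark = ",")
  ))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf(
      "  trained %d epochs; final loss %.4f, accuracy %.3f%s\n",
      nrow(x$history), last$loss, last$acc,
      if (!is.na(last$val_acc)) {
        sprintf(" (val %.3f)", last$val_acc)
      } else ""
    ))
  } else {
    cat("  untrained (initialized weights)\n")
  }
  invisible(x)
}

#' @export
summary.tcn_lstm <- function(object, ...) {
  cp <- count_params(object$spec)
  print(object)
  cat("\nLayer census:\n")
  print(cp$layers, row.names = FALSE)
  invisible(cp)
}

#' @export
coef.tcn_lstm <- function(object, ...) object$params

#' @export
plot.tcn_lstm <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "Cross-entropy", ...)
  if (any(!is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  graphics::plot(h$epoch, h$acc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  if (any(!is.na(h$val_acc))) graphics::lines(h$epoch, h$val_acc, lty = 2)
  invisible(x)
}
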