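# Low-level neural network layers used by the TCN-LSTM classifier.
# Activations flow as (batch, time, channels) arrays; every layer provides
# a forward pass (caching what its backward pass needs) and an exact
# gradient. Correctness is pinned down by a finite-difference check in the
# test suite.

# --- causal 1-D convolution -----------------------------------------------
# Left ("causal") zero padding: output at time t depends on inputs at
# times <= t only, and the sequence length is preserved for any kernel
# size. W has dim (kernel, in_channels, out_channels).

conv1d_forward <- function(x, w, b) {
  d <- dim(x)
  batch <- d[1]; len <- d[2]
  k <- dim(w)[1]; c_in <- dim(w)[2]; c_out <- dim(w)[3]
  out <- array(rep(b, each = batch * len), c(batch, len, c_out))
  for (i in 0:(k - 1)) {
    if (i + 1 > len) break
    ts <- (i + 1):len
    wi <- matrix(w[i + 1, , ], nrow = c_in)
    xm <- matrix(x[, ts - i, , drop = FALSE], ncol = c_in)
    out[, ts, ] <- out[, ts, , drop = FALSE] +
      array(xm %*% wi, c(batch, length(ts), c_out))
  }
  out
}

conv1d_backward <- function(dout, x, w) {
  d <- dim(x)
  batch <- d[1]; len <- d[2]
  k <- dim(w)[1]; c_in <- dim(w)[2]; c_out <- dim(w)[3]
  dx <- array(0, dim(x))
  dw <- array(0, dim(w))
  db <- colSums(matrix(dout, ncol = c_out))
  for (i in 0:(k - 1)) {
    if (i + 1 > len) break
    ts <- (i + 1):len
    wi <- matrix(w[i + 1, , ], nrow = c_in)
    xm <- matrix(x[, ts - i, , drop = FALSE], ncol = c_in)
    dom <- matrix(dout[, ts, , drop = FALSE], ncol = c_out)
    dw[i + 1, , ] <- crossprod(xm, dom)
    dx[, ts - i, ] <- dx[, ts - i, , drop = FALSE] +
      array(dom %*% t(wi), c(batch, length(ts), c_in))
  }
  list(dx = dx, dw = dw, db = db)
}

# --- batch normalization ---------------------------------------------------
# Normalizes per channel over batch and time. Training uses batch
# statistics and updates the (non-trainable) moving mean/variance;
# inference uses the moving statistics, making the layer a fixed
# per-channel affine map.

batchnorm_forward <- function(x, gamma, beta, rmean, rvar,
                              training = FALSE, momentum = 0.99,
                              eps = 1e-3) {
  d <- dim(x)
  c_n <- d[3]
  xm <- matrix(x, ncol = c_n)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * va
  } else {
    mu <- rmean
    va <- rvar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
  ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(
    out = array(ym, d),
    cache = list(xhat = xhat, istd = istd, gamma = gamma, dims = d,
                 training = training),
    rmean = rmean, rvar = rvar
  )
}

batchnorm_backward <- function(dout, cache) {
  d <- cache$dims
  c_n <- d[3]
  m <- d[1] * d[2]
  dym <- matrix(dout, ncol = c_n)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (cache$training) {
    t1 <- sweep(dym, 2, dbeta / m)
    t2 <- sweep(cache$xhat, 2, dgamma / m, "*")
    dxm <- sweep(t1 - t2, 2, cache$gamma * cache$istd, "*")
  } else {
    dxm <- sweep(dym, 2, cache$gamma * cache$istd, "*")
  }
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

# --- spatial dropout -------------------------------------------------------
# Drops whole channels (the same channels across all time steps of a
# sample), scaling survivors by 1/(1-p). Identity at inference.

spatial_dropout_forward <- function(x, p, training = FALSE) {
  if (!training || p <= 0) {
    return(list(out = x, mask = NULL))
  }
  d <- dim(x)
  keep <- matrix(stats::runif(d[1] * d[3]) >= p, d[1], d[3]) / (1 - p)
  mask <- aperm(array(keep, c(d[1], d[3], d[2])), c(1, 3, 2))
  list(out = x * mask, mask = mask)
}

dropout_forward <- function(x, p, training = FALSE) {
  if (!training || p <= 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- array(stats::runif(length(x)) >= p, dim(x)) / (1 - p)
  list(out = x * mask, mask = mask)
}

# --- LSTM ------------------------------------------------------------------
# Single-layer LSTM consuming the full sequence and emitting its final
# hidden state. Gate order in the packed weight matrices is (input,
# forget, cell, output); wx is (c_in, 4H), wh is (H, 4H).

lstm_forward <- function(x, wx, wh, b) {
  d <- dim(x)
  batch <- d[1]; len <- d[2]
  h_units <- ncol(wh) / 4L
  h <- matrix(0, batch, h_units)
  cc <- matrix(0, batch, h_units)
  steps <- vector("list", len)
  idx <- function(g) ((g - 1L) * h_units + 1L):(g * h_units)
  for (t in seq_len(len)) {
    xt <- matrix(x[, t, ], nrow = batch)
    z <- xt %*% wx + h %*% wh + matrix(b, batch, 4L * h_units, byrow = TRUE)
    gi <- 1 / (1 + exp(-z[, idx(1), drop = FALSE]))
    gf <- 1 / (1 + exp(-z[, idx(2), drop = FALSE]))
    gg <- tanh(z[, idx(3), drop = FALSE])
    go <- 1 / (1 + exp(-z[, idx(4), drop = FALSE]))
    c_new <- gf * cc + gi * gg
    h_new <- go * tanh(c_new)
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, gi = gi, gf = gf,
                       gg = gg, go = go, c_new = c_new)
    h <- h_new
    cc <- c_new
  }
  list(out = h, steps = steps, dims = d)
}

lstm_backward <- function(dh_last, cache, wx, wh) {
  d <- cache$dims
  batch <- d[1]; len <- d[2]
  h_units <- ncol(wh) / 4L
  dwx <- matrix(0, nrow(wx), ncol(wx))
  dwh <- matrix(0, nrow(wh), ncol(wh))
  db <- numeric(4L * h_units)
  dx <- array(0, d)
  dh <- dh_last
  dc <- matrix(0, batch, h_units)
  for (t in rev(seq_len(len))) {
    s <- cache$steps[[t]]
    tc <- tanh(s$c_new)
    dgo <- dh * tc
    dc <- dc + dh * s$go * (1 - tc^2)
    dgi <- dc * s$gg
    dgg <- dc * s$gi
    dgf <- dc * s$c_prev
    dc_prev <- dc * s$gf
    dz <- cbind(
      dgi * s$gi * (1 - s$gi),
      dgf * s$gf * (1 - s$gf),
      dgg * (1 - s$gg^2),
      dgo * s$go * (1 - s$go)
    )
    dwx <- dwx + crossprod(s$xt, dz)
    dwh <- dwh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(wx)
    dh <- dz %*% t(wh)
    dc <- dc_prev
  }
  list(dx = dx, dwx = dwx, dwh = dwh, db = db)
}

# --- dense / softmax -------------------------------------------------------

dense_forward <- function(x, w, b) {
  x %*% w + matrix(b, nrow(x), length(b), byrow = TRUE)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean categorical cross-entropy and its gradient w.r.t. the logits.
softmax_crossentropy <- function(logits, onehot) {
  p <- softmax(logits)
  eps <- 1e-12
  loss <- -sum(onehot * log(p + eps)) / nrow(logits)
  list(loss = loss, probs = p, dlogits = (p - onehot) / nrow(logits))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7, skip = character(0)) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- initializers ----------------------------------------------------------

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

orthogonal_init <- function(nrow_, ncol_) {
  a <- matrix(stats::rnorm(nrow_ * ncol_), nrow_, ncol_)
  qr_ <- qr(a)
  q <- qr.Q(qr_)
  q * sign(diag(qr.R(qr_)))[col(q)]
}
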