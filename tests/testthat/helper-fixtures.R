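# Shared fixtures, built in code at test time.

single_band_profile <- function(band, label = "X", noise_sd = 0, ...) {
  w <- stats::setNames(1, band)
  class_profile(label, w, noise_sd = noise_sd, ...)
}

# Random labelled feature matrix (not necessarily valid RBP rows).
random_features <- function(n, labels, p = 6, seed = 1,
                            bands = band_scheme("modified")$band) {
  set.seed(seed)
  rbp_features(
    matrix(runif(n * p), n, p), bands[seq_len(p)],
    sample(labels, n, replace = TRUE),
    sprintf("s%02d", sample.int(max(3, n %/% 10), n, replace = TRUE))
  )
}

# Direct single-segment periodogram band fractions: the independent
# oracle for Welch-based RBP on short fixtures.
periodogram_rbp <- function(x, fs, scheme = band_scheme("modified")) {
  n <- length(x)
  sp <- abs(stats::fft(x - mean(x)))^2
  freqs <- (0:(n - 1)) * fs / n
  half <- freqs <= fs / 2
  sp <- sp[half]
  freqs <- freqs[half]
  total <- sum(sp[freqs >= attr(scheme, "total_lo") &
                    freqs <= attr(scheme, "total_hi")])
  vapply(seq_len(nrow(scheme)), function(i) {
    inb <- freqs >= scheme$lo[i] &
      (if (scheme$hi_inclusive[i]) freqs <= scheme$hi[i] else
         freqs < scheme$hi[i])
    sum(sp[inb]) / total
  }, 0)
}

# Feature matrix with two classes separated in one column, everything
# else uninformative; used for fast classifier checks.
separable_features <- function(n_per_class = 150, sep_col = 5, seed = 1) {
  set.seed(seed)
  p <- 6
  a <- matrix(runif(n_per_class * p, 0.3, 0.7), n_per_class, p)
  b <- matrix(runif(n_per_class * p, 0.3, 0.7), n_per_class, p)
  a[, sep_col] <- runif(n_per_class, 0.05, 0.35)
  b[, sep_col] <- runif(n_per_class, 0.65, 0.95)
  x <- rbind(a, b)
  colnames(x) <- band_scheme("modified")$band
  list(x = x, y = rep(c("A", "B"), each = n_per_class))
}

# Brute-force per-sample counting oracle for classification metrics.
oracle_metrics <- function(truth, predicted, classes) {
  per_class <- lapply(classes, function(cl) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(truth)) {
      is_pos <- truth[i] == cl
      pred_pos <- predicted[i] == cl
      if (is_pos && pred_pos) tp <- tp + 1L
      if (!is_pos && pred_pos) fp <- fp + 1L
      if (is_pos && !pred_pos) fn <- fn + 1L
      if (!is_pos && !pred_pos) tn <- tn + 1L
    }
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    data.frame(
      class = cl, precision = prec, recall = rec,
      f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
      specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
      support = tp + fn
    )
  })
  list(
    accuracy = mean(truth == predicted),
    per_class = do.call(rbind, per_class)
  )
}

# Rank-sum (Mann-Whitney) AUC oracle: brute force over all pairs.
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}
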