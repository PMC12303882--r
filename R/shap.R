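# Model-agnostic Shapley-value attributions. With the six band-power
# features of this pipeline the coalition space is tiny (2^6 = 64), so
# Shapley values are computed exactly by full enumeration against a
# background distribution: v(S) is the mean model output when the features
# in S come from the explained instance and the rest from each background
# row. Local accuracy (base value + sum of attributions = model output)
# then holds exactly, not approximately.

#' Summarize a training set into a Shapley background
#'
#' K-means centroids of the training features, giving a compact background
#' distribution for [shap_values()].
#'
#' @param x feature matrix or [rbp_features()] object.
#' @param n number of centroids (capped at the number of distinct rows).
#' @param seed integer seed for k-means.
#' @return Matrix of background rows.
#' @export
shap_background <- function(x, n = 20, seed = 1) {
  if (inherits(x, "rbp_features")) x <- x$values
  x <- as.matrix(x)
  ux <- unique(x)
  if (nrow(ux) <= n) return(ux)
  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = n, nstart = 3, iter.max = 50)
  unname(km$centers)
}

# Shapley kernel weights: weight of a coalition of size s (out of p
# features) in the marginal-contribution sum, s! (p-s-1)! / p!.
shapley_weights <- function(p) {
  s <- 0:(p - 1)
  exp(lfactorial(s) + lfactorial(p - s - 1) - lfactorial(p))
}

#' Exact Shapley-value feature attributions
#'
#' Computes, for every instance and output class, the exact Shapley value
#' of each feature with respect to the model's predicted probability,
#' using full coalition enumeration over the feature set and averaging
#' over a background distribution. The base value of a class is the mean
#' prediction over the background; base value plus attributions reproduce
#' the model output exactly.
#'
#' @param object a fitted [tcn_lstm()] model, or a function mapping a
#'   feature matrix to a matrix of outputs (one column per class).
#' @param x instances to explain (matrix or [rbp_features()]).
#' @param background background rows, e.g. from [shap_background()].
#' @param feature_names column names (defaults to those of `x`).
#' @param ... unused.
#' @return Object of class `shap_attribution`: list with `values`
#'   (instances x features x classes array), `base_values` (per class),
#'   `feature_values` (the explained instances), `feature_names`,
#'   `class_order`.
#' @export
shap_values <- function(object, x, background, ...) {
  UseMethod("shap_values")
}

#' @rdname shap_values
#' @export
shap_values.tcn_lstm <- function(object, x, background, ...) {
  f <- function(m) predict(object, m, type = "prob")
  res <- shap_values.function(f, x, background, ...)
  dimnames(res$values)[[3]] <- object$class_order
  res$class_order <- object$class_order
  names(res$base_values) <- object$class_order
  res
}

#' @rdname shap_values
#' @param feature_names feature names used in reports.
#' @export
shap_values.function <- function(object, x, background,
                                 feature_names = NULL, ...) {
  if (inherits(x, "rbp_features")) {
    if (is.null(feature_names)) feature_names <- x$band_names
    x <- x$values
  }
  x <- as.matrix(x)
  background <- as.matrix(background)
  if (!nrow(background)) stop("empty background")
  p <- ncol(x)
  if (ncol(background) != p) {
    stop("background feature width must match x")
  }
  if (p > 16) {
    stop("exact enumeration supports at most 16 features (got ", p, ")")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(x) %||% paste0("f", seq_len(p))
  }

  n_bg <- nrow(background)
  n_mask <- 2L^p
  # mask matrix: row m is the coalition with id m-1, bit j = feature j
  masks <- matrix(FALSE, n_mask, p)
  for (j in seq_len(p)) {
    masks[, j] <- bitwAnd(seq_len(n_mask) - 1L, bitwShiftL(1L, j - 1L)) != 0L
  }
  w <- shapley_weights(p)

  # probe the output dimension
  probe <- object(x[1, , drop = FALSE])
  n_cls <- ncol(as.matrix(probe))
  class_order <- colnames(as.matrix(probe)) %||% paste0("class", seq_len(n_cls))

  base_values <- colMeans(as.matrix(object(background)))
  values <- array(
    0, c(nrow(x), p, n_cls),
    dimnames = list(NULL, feature_names, class_order)
  )
  bg_big <- background[rep(seq_len(n_bg), n_mask), , drop = FALSE]
  mask_big <- masks[rep(seq_len(n_mask), each = n_bg), , drop = FALSE]
  mask_id <- rep(seq_len(n_mask), each = n_bg)

  for (i in seq_len(nrow(x))) {
    z <- bg_big
    xi <- matrix(x[i, ], nrow(z), p, byrow = TRUE)
    z[mask_big] <- xi[mask_big]
    preds <- as.matrix(object(z))
    # v(S): mean prediction per coalition
    v <- rowsum(preds, mask_id, reorder = TRUE) / n_bg
    sizes <- rowSums(masks)
    for (j in seq_len(p)) {
      without <- which(!masks[, j])
      with_j <- without + bitwShiftL(1L, j - 1L)
      wj <- w[sizes[without] + 1L]
      values[i, j, ] <- colSums(
        wj * (v[with_j, , drop = FALSE] - v[without, , drop = FALSE])
      )
    }
  }
  structure(
    list(
      values = values, base_values = base_values,
      feature_values = x, feature_names = feature_names,
      class_order = class_order
    ),
    class = "shap_attribution"
  )
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf(
    "shap_attribution: %d instances x %d features x %d classes\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]
  ))
  cat("mean |value| by feature (all classes):\n")
  imp <- apply(abs(x$values), 2, mean)
  print(round(sort(imp, decreasing = TRUE), 4))
  invisible(x)
}

#' Global feature importance for one class
#'
#' Mean absolute Shapley value per feature, sorted descending — the
#' statistic shown in global-importance bar charts.
#'
#' @param attr a [shap_values()] result.
#' @param class class name (must appear in `attr$class_order`).
#' @return Data frame with `feature` and `importance`, sorted descending.
#' @export
global_importance <- function(attr, class) {
  stopifnot(inherits(attr, "shap_attribution"))
  k <- match(class, attr$class_order)
  if (is.na(k)) stop("unknown class '", class, "'")
  imp <- apply(abs(attr$values[, , k, drop = FALSE]), 2, mean)
  out <- data.frame(
    feature = attr$feature_names, importance = unname(imp),
    stringsAsFactors = FALSE
  )
  out[order(out$importance, decreasing = TRUE), , drop = FALSE]
}

#' Per-instance data behind a beeswarm summary plot
#'
#' @param attr a [shap_values()] result.
#' @param class class name.
#' @return Data frame with one row per (instance, feature):
#'   `instance`, `feature`, `feature_value`, `shap_value`.
#' @export
summary_data <- function(attr, class) {
  stopifnot(inherits(attr, "shap_attribution"))
  k <- match(class, attr$class_order)
  if (is.na(k)) stop("unknown class '", class, "'")
  n <- dim(attr$values)[1]
  p <- dim(attr$values)[2]
  data.frame(
    instance = rep(seq_len(n), p),
    feature = rep(attr$feature_names, each = n),
    feature_value = as.vector(attr$feature_values),
    shap_value = as.vector(attr$values[, , k]),
    stringsAsFactors = FALSE
  )
}

#' Instance-by-feature attribution matrix for heatmap display
#'
#' @param attr a [shap_values()] result.
#' @param class class name.
#' @return List with `matrix` (instances x features Shapley values) and
#'   `importance` (the per-feature global importance shown as the heatmap
#'   sidebar).
#' @export
heatmap_data <- function(attr, class) {
  stopifnot(inherits(attr, "shap_attribution"))
  k <- match(class, attr$class_order)
  if (is.na(k)) stop("unknown class '", class, "'")
  m <- attr$values[, , k]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  colnames(m) <- attr$feature_names
  list(matrix = m, importance = apply(abs(m), 2, mean))
}

#' Plot global feature importance as a bar chart
#' @param attr a [shap_values()] result.
#' @param class class name.
#' @param file optional PNG path; plots to the active device when NULL.
#' @export
plot_importance <- function(attr, class, file = NULL) {
  gi <- global_importance(attr, class)
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 450)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(
    rev(gi$importance), names.arg = rev(gi$feature), horiz = TRUE,
    las = 1, xlab = "mean |SHAP value|",
    main = sprintf("Global feature importance: %s", class)
  )
  invisible(gi)
}

#' Plot a beeswarm-style attribution summary
#' @inheritParams plot_importance
#' @export
plot_beeswarm <- function(attr, class, file = NULL) {
  sd_ <- summary_data(attr, class)
  gi <- global_importance(attr, class)
  feats <- rev(gi$feature)
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 450)
    on.exit(grDevices::dev.off())
  }
  set.seed(1) # jitter only
  y <- match(sd_$feature, feats) + stats::runif(nrow(sd_), -0.2, 0.2)
  rng <- range(sd_$feature_value)
  rel <- if (diff(rng) > 0) (sd_$feature_value - rng[1]) / diff(rng) else 0.5
  cols <- grDevices::rgb(rel, 0.2, 1 - rel, alpha = 0.6)
  graphics::plot(
    sd_$shap_value, y, pch = 16, cex = 0.6, col = cols, yaxt = "n",
    xlab = "SHAP value", ylab = "",
    main = sprintf("SHAP summary: %s", class)
  )
  graphics::axis(2, at = seq_along(feats), labels = feats, las = 1)
  graphics::abline(v = 0, lty = 3)
  invisible(sd_)
}

#' Plot an instance-by-feature attribution heatmap
#' @inheritParams plot_importance
#' @export
plot_heatmap <- function(attr, class, file = NULL) {
  hd <- heatmap_data(attr, class)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 450)
    on.exit(grDevices::dev.off())
  }
  m <- hd$matrix
  lim <- max(abs(m), 1e-12)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::layout(matrix(1:2, 1), widths = c(4, 1))
  graphics::image(
    seq_len(nrow(m)), seq_len(ncol(m)), m, zlim = c(-lim, lim), col = pal,
    xlab = "instance", ylab = "", yaxt = "n",
    main = sprintf("SHAP heatmap: %s", class)
  )
  graphics::axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 1)
  graphics::barplot(hd$importance, horiz = TRUE, names.arg = NA,
                    xlab = "mean |SHAP|")
  graphics::layout(1)
  invisible(hd)
}
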