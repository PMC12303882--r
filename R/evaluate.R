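#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted label vectors of equal length; every value must
#'   appear in `class_order`.
#' @param class_order fixed class ordering for rows (truth) and columns
#'   (prediction); defaults to the sorted union of the labels.
#' @return Object of class `confusion_matrix`: an integer matrix with
#'   `counts[i, j]` the number of instances of true class `i` predicted as
#'   class `j`.
#' @export
confusion <- function(truth, predicted, class_order = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("'truth' and 'predicted' must have equal length")
  }
  if (is.null(class_order)) class_order <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), class_order)
  if (length(bad)) {
    stop("label(s) not in class_order: ", paste(bad, collapse = ", "))
  }
  tf <- factor(truth, levels = class_order)
  pf <- factor(predicted, levels = class_order)
  counts <- unclass(table(tf, pf))
  dimnames(counts) <- list(truth = class_order, predicted = class_order)
  structure(counts, class = c("confusion_matrix", class(counts)))
}

#' Build a confusion matrix directly from counts
#' @param counts square integer matrix (rows = truth, cols = predicted).
#' @param class_order class names.
#' @export
as_confusion <- function(counts, class_order = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("'counts' must be square")
  if (is.null(class_order)) {
    class_order <- paste0("class", seq_len(nrow(counts)))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(truth = class_order, predicted = class_order)
  structure(counts, class = c("confusion_matrix", class(counts)))
}

#' Per-class metrics from a confusion matrix
#'
#' Each class is evaluated one-vs-rest: precision `TP/(TP+FP)`, recall
#' (equal to sensitivity) `TP/(TP+FN)`, F1 as their harmonic mean, and
#' specificity `TN/(TN+FP)`. Overall accuracy is the trace over the total.
#' Zero denominators yield 0 with a warning.
#'
#' @param cm a [confusion()] matrix.
#' @return Object of class `metric_report`: list with `accuracy`,
#'   `per_class` data frame (precision, recall, f1, sensitivity,
#'   specificity, support), and `class_order`.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- unclass(cm)
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(counts)
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warning(sprintf("%s undefined for class %s (zero denominator); using 0",
                      what, cl))
      return(0)
    }
    num / den
  }
  rows <- lapply(seq_along(classes), function(i) {
    tp <- counts[i, i]
    fn <- sum(counts[i, -i])
    fp <- sum(counts[-i, i])
    tn <- total - tp - fn - fp
    precision <- safe_div(tp, tp + fp, "precision", classes[i])
    recall <- safe_div(tp, tp + fn, "recall", classes[i])
    f1 <- if (precision + recall == 0) 0 else {
      2 * precision * recall / (precision + recall)
    }
    specificity <- safe_div(tn, tn + fp, "specificity", classes[i])
    data.frame(
      class = classes[i], precision = precision, recall = recall, f1 = f1,
      sensitivity = recall, specificity = specificity,
      support = tp + fn, stringsAsFactors = FALSE
    )
  })
  structure(
    list(
      accuracy = sum(diag(counts)) / total,
      per_class = do.call(rbind, rows),
      class_order = classes
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("Accuracy: %.*f\n", digits, x$accuracy))
  pc <- x$per_class
  for (col in c("precision", "recall", "f1", "sensitivity", "specificity")) {
    pc[[col]] <- round(pc[[col]], digits)
  }
  print(pc, row.names = FALSE)
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For every class, sweeps a threshold over that class's predicted
#' probability and integrates the ROC curve with the trapezoid rule. Tied
#' scores are handled by grouping, so the AUC equals the rank-sum
#' (Mann-Whitney) statistic divided by `n_pos * n_neg`.
#'
#' @param truth true labels (character/factor) or a one-hot matrix with
#'   class columns.
#' @param probs matrix of predicted class probabilities, columns in
#'   `class_order`.
#' @param class_order class names; defaults to `colnames(probs)`.
#' @return Object of class `roc_result`: list with `auc` (named vector,
#'   `NA` for a class absent from the truth) and `curves` (per-class data
#'   frames of `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(truth, probs, class_order = colnames(probs)) {
  probs <- as.matrix(probs)
  if (is.null(class_order)) {
    stop("'class_order' required when probs has no column names")
  }
  if (is.matrix(truth) || is.data.frame(truth)) {
    truth <- class_order[max.col(as.matrix(truth))]
  }
  truth <- as.character(truth)
  if (length(truth) != nrow(probs)) {
    stop("'truth' length must match nrow(probs)")
  }
  if (anyNA(probs) || any(!is.finite(probs))) {
    stop("'probs' must be finite scores")
  }
  auc <- stats::setNames(rep(NA_real_, length(class_order)), class_order)
  curves <- stats::setNames(vector("list", length(class_order)), class_order)
  for (k in seq_along(class_order)) {
    pos <- truth == class_order[k]
    n_pos <- sum(pos)
    n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) next
    sc <- probs[, k]
    ord <- order(sc, decreasing = TRUE)
    sc_o <- sc[ord]
    pos_o <- pos[ord]
    # group tied scores: one operating point per distinct threshold
    last_of_group <- c(sc_o[-1] != sc_o[-length(sc_o)], TRUE)
    tpr <- c(0, cumsum(pos_o)[last_of_group] / n_pos)
    fpr <- c(0, cumsum(!pos_o)[last_of_group] / n_neg)
    auc[k] <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    curves[[k]] <- data.frame(
      threshold = c(Inf, sc_o[last_of_group]), fpr = fpr, tpr = tpr
    )
  }
  structure(list(auc = auc, curves = curves), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("One-vs-rest AUC:\n")
  for (k in names(x$auc)) {
    cat(sprintf(
      "  %-16s %s\n", k,
      if (is.na(x$auc[k])) "NA (class absent)" else sprintf("%.4f", x$auc[k])
    ))
  }
  invisible(x)
}

#' K-fold cross-validated accuracy of the TCN-LSTM classifier
#'
#' Trains a fresh model on every fold (normalization fitted on that fold's
#' training rows only) and reports per-fold training and test accuracy.
#'
#' @param fm an [rbp_features()] object (all rows must belong to the
#'   task).
#' @param task classification task 1-4 (see [task_classes()]).
#' @param k number of folds.
#' @param spec optional [model_spec()].
#' @param control a [train_control()].
#' @param seed seed for the fold partition.
#' @return Data frame with one row per fold (`fold`, `train_acc`,
#'   `test_acc`) and attributes `mean` and `sd` of the test accuracy.
#' @export
crossval_report <- function(fm, task = 1, k = 5, spec = NULL,
                            control = train_control(), seed = 1) {
  stopifnot(inherits(fm, "rbp_features"))
  fm <- subset_task(fm, task)
  labels <- map_task_labels(fm$labels, task)
  folds <- kfold_partition(fm, k = k, seed = seed)
  rows <- lapply(seq_along(folds), function(f) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    res <- tryCatch({
      mm <- fit_minmax(fm$values[tr, , drop = FALSE])
      xtr <- apply_minmax(fm$values[tr, , drop = FALSE], mm)
      xte <- apply_minmax(fm$values[te, , drop = FALSE], mm)
      fit <- tcn_lstm(xtr, labels[tr], spec = spec, control = control)
      data.frame(
        fold = f,
        train_acc = mean(predict(fit, xtr, type = "class") == labels[tr]),
        test_acc = mean(predict(fit, xte, type = "class") == labels[te])
      )
    }, error = function(e) {
      stop("fold ", f, ": ", conditionMessage(e), call. = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "mean") <- mean(out$test_acc)
  attr(out, "sd") <- stats::sd(out$test_acc)
  out
}
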