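# Dataset preparation: task-dependent label encoding, min-max
# normalization, stratified train/val/test splitting, SMOTE balancing and
# stratified k-fold partitioning.

#' Class orders for the four classification tasks
#'
#' Task 1: AD vs FTD vs HC (three classes). Task 2: AD and FTD merged into
#' a single "Dementia" class vs HC. Task 3: AD vs HC. Task 4: FTD vs HC.
#'
#' @param task integer 1-4.
#' @return Character vector of class names in fixed (alphabetical) order.
#' @export
task_classes <- function(task) {
  if (!task %in% 1:4) stop("'task' must be 1, 2, 3 or 4")
  switch(task,
    c("AD", "FTD", "HC"),
    c("Dementia", "HC"),
    c("AD", "HC"),
    c("FTD", "HC")
  )
}

# Map raw AD/FTD/HC labels onto a task's classes; labels outside the task
# are an error (rows must be pre-filtered, see subset_task()).
map_task_labels <- function(labels, task) {
  if (!task %in% 1:4) stop("'task' must be 1, 2, 3 or 4")
  unknown <- setdiff(unique(labels), c("AD", "FTD", "HC"))
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  if (task == 2) {
    labels[labels %in% c("AD", "FTD")] <- "Dementia"
  }
  bad <- setdiff(unique(labels), task_classes(task))
  if (length(bad)) {
    stop(
      "label(s) not part of task ", task, ": ",
      paste(bad, collapse = ", "), " (filter rows first, see subset_task)"
    )
  }
  labels
}

#' Drop feature rows whose class is not part of a task
#'
#' @param fm an [rbp_features()] object with AD/FTD/HC labels.
#' @param task integer 1-4 (see [task_classes()]).
#' @return The subset [rbp_features()] object.
#' @export
subset_task <- function(fm, task) {
  stopifnot(inherits(fm, "rbp_features"))
  if (!task %in% 1:4) stop("'task' must be 1, 2, 3 or 4")
  keep <- switch(task,
    fm$labels %in% c("AD", "FTD", "HC"),
    fm$labels %in% c("AD", "FTD", "HC"),
    fm$labels %in% c("AD", "HC"),
    fm$labels %in% c("FTD", "HC")
  )
  subset_features(fm, keep)
}

#' One-hot encode class labels for a classification task
#'
#' Merges classes as the task requires (AD and FTD become "Dementia" for
#' task 2), then encodes each label as a one-hot row over the task's fixed
#' alphabetical class order.
#'
#' @param labels character vector of AD/FTD/HC labels.
#' @param task integer 1-4 (see [task_classes()]).
#' @return List with `onehot` (n x n_classes 0/1 matrix), `class_order`,
#'   and `labels` (the task-mapped labels).
#' @export
encode_labels <- function(labels, task = 1) {
  mapped <- map_task_labels(as.character(labels), task)
  classes <- task_classes(task)
  onehot <- matrix(0L, length(mapped), length(classes),
                   dimnames = list(NULL, classes))
  onehot[cbind(seq_along(mapped), match(mapped, classes))] <- 1L
  list(onehot = onehot, class_order = classes, labels = mapped)
}

#' Fit min-max normalization parameters
#'
#' @param x numeric matrix (training features) or an [rbp_features()]
#'   object.
#' @return Object of class `minmax_params` with per-feature `min` and
#'   `max`.
#' @export
fit_minmax <- function(x) {
  if (inherits(x, "rbp_features")) x <- x$values
  x <- as.matrix(x)
  structure(
    list(min = apply(x, 2, min), max = apply(x, 2, max)),
    class = "minmax_params"
  )
}

#' Apply min-max normalization
#'
#' Maps each feature through `(x - min) / (max - min)` using parameters
#' fitted on the training partition; held-out values may fall outside
#' `[0, 1]`. A constant training feature (max == min) maps to 0 with a
#' warning.
#'
#' @param x numeric matrix or [rbp_features()] object.
#' @param params a [fit_minmax()] result.
#' @return Same type as `x`, normalized.
#' @export
apply_minmax <- function(x, params) {
  stopifnot(inherits(params, "minmax_params"))
  fm <- NULL
  if (inherits(x, "rbp_features")) {
    fm <- x
    x <- x$values
  }
  x <- as.matrix(x)
  rng <- params$max - params$min
  if (any(rng == 0)) {
    warning("constant feature(s) map to 0: ",
            paste(which(rng == 0), collapse = ", "))
  }
  out <- sweep(x, 2, params$min)
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  if (!is.null(fm)) {
    fm$values <- out
    fm
  } else {
    out
  }
}

# Largest-remainder allocation of n items over fractions fr (sums to n).
alloc_counts <- function(n, fr) {
  raw <- n * fr
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Split a feature matrix into train/validation/test partitions
#'
#' Disjoint and exhaustive; stratified by class by default. In
#' `"subject"` mode whole subjects (all their epochs) are assigned to one
#' partition, which prevents epochs of the same recording leaking across
#' partitions.
#'
#' @param fm an [rbp_features()] object.
#' @param train,val,test partition fractions (must sum to 1).
#' @param seed integer seed; identical seeds give identical partitions.
#' @param mode `"epoch"` (default) or `"subject"`.
#' @param stratified stratify by class (default TRUE).
#' @return List with `train`, `val`, `test` ([rbp_features()] objects) and
#'   an `indices` attribute giving the row indices of each partition.
#' @export
split_features <- function(fm, train = 0.8, val = 0.1, test = 0.1,
                           seed = 1, mode = c("epoch", "subject"),
                           stratified = TRUE) {
  stopifnot(inherits(fm, "rbp_features"))
  mode <- match.arg(mode)
  fr <- c(train, val, test)
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(as.integer(seed))
  n <- nrow(fm$values)

  assign_units <- function(units, strata) {
    part <- integer(length(units))
    groups <- if (stratified) split(seq_along(units), strata) else
      list(seq_along(units))
    for (g in groups) {
      g <- g[sample.int(length(g))]
      cnt <- alloc_counts(length(g), fr)
      part[g] <- rep(1:3, times = cnt)
    }
    part
  }

  if (mode == "epoch") {
    part <- assign_units(seq_len(n), fm$labels)
  } else {
    subj <- unique(fm$subject_ids)
    subj_lab <- fm$labels[match(subj, fm$subject_ids)]
    spart <- assign_units(subj, subj_lab)
    part <- spart[match(fm$subject_ids, subj)]
  }
  idx <- lapply(1:3, function(p) which(part == p))
  out <- list(
    train = subset_features(fm, idx[[1]]),
    val = subset_features(fm, idx[[2]]),
    test = subset_features(fm, idx[[3]])
  )
  attr(out, "indices") <- stats::setNames(idx, c("train", "val", "test"))
  out
}

#' Balance classes with SMOTE oversampling
#'
#' Every minority class is grown to the majority-class count. Each
#' synthetic row is `x + u * (x_nn - x)` with `u ~ U(0, 1)`, where `x` is
#' a minority row and `x_nn` one of its `k_neighbors` nearest within-class
#' neighbours (Euclidean distance, ties broken by row index). Original
#' rows are preserved unchanged, first, in their input order.
#'
#' @param fm an [rbp_features()] object.
#' @param k_neighbors neighbourhood size (default 5).
#' @param seed integer seed.
#' @return A balanced [rbp_features()] object.
#' @export
smote_balance <- function(fm, k_neighbors = 5, seed = 1) {
  stopifnot(inherits(fm, "rbp_features"))
  tab <- table(fm$labels)
  target <- max(tab)
  if (all(tab == target)) return(fm)
  set.seed(as.integer(seed))
  new_vals <- list()
  new_labs <- character(0)
  new_subj <- character(0)
  for (cl in names(tab)) {
    need <- target - tab[[cl]]
    if (need == 0) next
    ridx <- which(fm$labels == cl)
    m <- fm$values[ridx, , drop = FALSE]
    n_c <- nrow(m)
    if (n_c <= k_neighbors) {
      stop(
        "class '", cl, "' has ", n_c, " rows; needs more than ",
        k_neighbors, " for SMOTE with k_neighbors = ", k_neighbors
      )
    }
    d <- as.matrix(stats::dist(m))
    diag(d) <- Inf
    # k nearest within-class neighbours per row, ties broken by row index
    nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
    base <- sample.int(n_c, need, replace = TRUE)
    pick <- sample.int(k_neighbors, need, replace = TRUE)
    u <- stats::runif(need)
    x <- m[base, , drop = FALSE]
    xnn <- m[nn[cbind(base, pick)], , drop = FALSE]
    new_vals[[cl]] <- x + u * (xnn - x)
    new_labs <- c(new_labs, rep(cl, need))
    new_subj <- c(new_subj, paste0(fm$subject_ids[ridx][base], "_smote"))
  }
  rbp_features(
    rbind(fm$values, do.call(rbind, new_vals)),
    fm$band_names,
    c(fm$labels, new_labs),
    c(fm$subject_ids, new_subj)
  )
}

#' Stratified k-fold partition
#'
#' Folds are disjoint, exhaustive, stratified by class, and their sizes
#' differ by at most one row.
#'
#' @param fm an [rbp_features()] object.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return List of `k` elements, each a list with `train` and `test` row
#'   index vectors.
#' @export
kfold_partition <- function(fm, k = 5, seed = 1) {
  stopifnot(inherits(fm, "rbp_features"))
  n <- nrow(fm$values)
  if (k < 2) stop("'k' must be >= 2")
  if (k > n) stop("'k' exceeds the number of rows (", n, ")")
  set.seed(as.integer(seed))
  fold <- integer(n)
  sizes <- integer(k)
  for (g in split(seq_len(n), fm$labels)) {
    g <- g[sample.int(length(g))]
    n_g <- length(g)
    q <- n_g %/% k
    r <- n_g %% k
    # every fold gets q rows; the r extras go to the currently smallest
    # folds so overall sizes stay within one of each other
    extras <- order(sizes)[seq_len(r)]
    cnt <- rep(q, k)
    cnt[extras] <- cnt[extras] + 1L
    fold[g] <- rep(seq_len(k), times = cnt)
    sizes <- sizes + cnt
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}
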