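#' Raw EEG container
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one name per row of `data`.
#' @param subject_id subject identifier string.
#' @param label optional class label (`"AD"`, `"FTD"`, `"HC"`, ...).
#' @return Object of class `raw_eeg`.
#' @export
raw_eeg <- function(data, fs, channel_names, subject_id = "unknown",
                    label = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("'data' must be numeric")
  if (nrow(data) == 0L) stop("format error: zero channels")
  if (anyNA(data)) stop("'data' contains NA/NaN values")
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be > 0")
  if (length(channel_names) != nrow(data)) {
    stop("length(channel_names) must equal nrow(data)")
  }
  structure(
    list(
      data = unname(data), fs = fs,
      channel_names = as.character(channel_names),
      subject_id = subject_id, label = label
    ),
    class = "raw_eeg"
  )
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf(
    "raw_eeg: %d channels x %d samples @ %g Hz (%.1f s), subject %s%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$subject_id,
    if (is.na(x$label)) "" else sprintf(", label %s", x$label)
  ))
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Dispatches on format: European Data Format (`.edf`) or EEGLAB (`.set`).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"`, or `"eeglab_set"`.
#' @return A [raw_eeg()] object with data in microvolts.
#' @export
read_eeg <- function(path, format = c("auto", "edf", "eeglab_set")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      edf = "edf",
      set = "eeglab_set",
      stop("format error: unknown extension '.", ext, "' for file ", path)
    )
  }
  switch(format,
    edf = read_edf(path),
    eeglab_set = read_eeglab_set(path)
  )
}

#' Relative band power feature matrix
#'
#' Rows are epochs, columns are bands; every row carries a class label and
#' the identifier of the subject the epoch came from (so subject-aware
#' splits can be audited).
#'
#' @param values epochs x bands numeric matrix of RBP fractions.
#' @param band_names ordered band names (column names).
#' @param labels per-epoch class labels.
#' @param subject_ids per-epoch subject identifiers.
#' @return Object of class `rbp_features`.
#' @export
rbp_features <- function(values, band_names, labels, subject_ids = NULL) {
  values <- as.matrix(values)
  if (length(band_names) != ncol(values)) {
    stop("length(band_names) must equal ncol(values)")
  }
  if (length(labels) != nrow(values)) {
    stop("length(labels) must equal nrow(values)")
  }
  if (is.null(subject_ids)) subject_ids <- rep(NA_character_, nrow(values))
  if (length(subject_ids) != nrow(values)) {
    stop("length(subject_ids) must equal nrow(values)")
  }
  colnames(values) <- band_names
  structure(
    list(
      values = values, band_names = as.character(band_names),
      labels = as.character(labels), subject_ids = as.character(subject_ids)
    ),
    class = "rbp_features"
  )
}

#' @export
print.rbp_features <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "rbp_features: %d epochs x %d bands (%s); classes: %s\n",
    nrow(x$values), ncol(x$values),
    paste(x$band_names, collapse = ", "),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

#' Subset a feature matrix by row index
#' @param fm an [rbp_features()] object.
#' @param idx integer or logical row index.
#' @export
subset_features <- function(fm, idx) {
  stopifnot(inherits(fm, "rbp_features"))
  rbp_features(
    fm$values[idx, , drop = FALSE], fm$band_names,
    fm$labels[idx], fm$subject_ids[idx]
  )
}

#' Write a feature matrix to CSV
#'
#' Comma separator, `.` decimal mark, UTF-8, mandatory header row. Columns
#' are the band names in order, then `Label`, then `Subject`.
#'
#' @param fm an [rbp_features()] object.
#' @param path output path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "rbp_features"))
  df <- as.data.frame(fm$values)
  names(df) <- fm$band_names
  df$Label <- fm$labels
  df$Subject <- fm$subject_ids
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV path as written by [write_feature_matrix()]; a `Label`
#'   column is mandatory, `Subject` optional, all remaining columns are
#'   bands.
#' @return An [rbp_features()] object.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"Label" %in% names(df)) {
    stop("schema error: missing 'Label' column in ", path)
  }
  bands <- setdiff(names(df), c("Label", "Subject"))
  if (!length(bands)) stop("schema error: no band columns in ", path)
  vals <- matrix(NA_real_, nrow(df), length(bands),
                 dimnames = list(NULL, bands))
  for (b in bands) {
    v <- suppressWarnings(as.numeric(df[[b]]))
    bad <- which(is.na(v) & !is.na(df[[b]]))
    if (length(bad)) {
      stop(sprintf(
        "schema error: non-numeric value '%s' at row %d, column '%s'",
        df[[b]][bad[1]], bad[1], b
      ))
    }
    vals[, b] <- v
  }
  rbp_features(
    vals, bands, df$Label,
    if ("Subject" %in% names(df)) df$Subject else NULL
  )
}
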