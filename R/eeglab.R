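# Minimal MAT v5 reader/writer covering the subset EEGLAB .set files use:
# uncompressed data elements holding numeric, char and struct arrays. The
# EEG struct's signal can live inline (EEG.data numeric) or in a sibling
# .fdt file of little-endian float32 samples; both are supported. MATLAB
# files written with compression (miCOMPRESSED elements) are rejected with
# a clear error rather than silently misread.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L

pad8 <- function(n) (8L - (n %% 8L)) %% 8L

mat5_write_element <- function(type, payload_raw) {
  n <- length(payload_raw)
  c(
    writeBin(c(as.integer(type), n), raw(), size = 4L, endian = "little"),
    payload_raw, raw(pad8(n))
  )
}

mat5_numeric_payload <- function(x) {
  writeBin(as.double(x), raw(), size = 8L, endian = "little")
}

# Serialize one miMATRIX element (numeric matrix, char vector, or struct
# given as a named list; struct arrays as an unnamed list of named lists).
mat5_matrix <- function(x, name = "") {
  name_el <- mat5_write_element(MI_INT8, charToRaw(name))
  if (is.character(x)) {
    s <- paste(x, collapse = "")
    dims <- c(1L, nchar(s))
    flags <- mat5_write_element(
      MI_UINT32,
      writeBin(c(MX_CHAR, 0L), raw(), size = 4L, endian = "little")
    )
    dim_el <- mat5_write_element(
      MI_INT32, writeBin(dims, raw(), size = 4L, endian = "little")
    )
    data_el <- mat5_write_element(
      MI_UINT16,
      writeBin(utf8ToInt(s), raw(), size = 2L, endian = "little")
    )
    body <- c(flags, dim_el, name_el, data_el)
  } else if (is.list(x)) {
    elems <- if (!is.null(names(x))) list(x) else x # struct array
    fields <- names(elems[[1]])
    dims <- c(1L, length(elems))
    flags <- mat5_write_element(
      MI_UINT32,
      writeBin(c(MX_STRUCT, 0L), raw(), size = 4L, endian = "little")
    )
    dim_el <- mat5_write_element(
      MI_INT32, writeBin(dims, raw(), size = 4L, endian = "little")
    )
    fnlen <- mat5_write_element(
      MI_INT32, writeBin(32L, raw(), size = 4L, endian = "little")
    )
    fname_raw <- raw(0)
    for (f in fields) {
      b <- charToRaw(f)
      fname_raw <- c(fname_raw, b, raw(32L - length(b)))
    }
    fnames <- mat5_write_element(MI_INT8, fname_raw)
    vals <- raw(0)
    for (el in elems) {
      for (f in fields) vals <- c(vals, mat5_matrix(el[[f]]))
    }
    body <- c(flags, dim_el, name_el, fnlen, fnames, vals)
  } else {
    x <- as.matrix(x)
    dims <- dim(x)
    flags <- mat5_write_element(
      MI_UINT32,
      writeBin(c(MX_DOUBLE, 0L), raw(), size = 4L, endian = "little")
    )
    dim_el <- mat5_write_element(
      MI_INT32, writeBin(as.integer(dims), raw(), size = 4L,
                         endian = "little")
    )
    data_el <- mat5_write_element(MI_DOUBLE, mat5_numeric_payload(x))
    body <- c(flags, dim_el, name_el, data_el)
  }
  mat5_write_element(MI_MATRIX, body)
}

#' Write a recording as an EEGLAB .set file
#'
#' Writes an uncompressed MAT v5 file holding an `EEG` struct with fields
#' `setname`, `nbchan`, `pnts`, `trials`, `srate`, `chanlocs` (labels) and
#' `data`. With `data_in_fdt = TRUE` the signal goes to a sibling `.fdt`
#' file of float32 samples and `EEG.data` holds its filename, mirroring
#' EEGLAB's two-file layout.
#'
#' @param raw a [raw_eeg()] object.
#' @param path output `.set` path.
#' @param data_in_fdt store samples in a separate `.fdt` file.
#' @export
write_eeglab_set <- function(raw, path, data_in_fdt = FALSE) {
  stopifnot(inherits(raw, "raw_eeg"))
  chanlocs <- lapply(raw$channel_names, function(nm) list(labels = nm))
  if (data_in_fdt) {
    fdt <- paste0(tools::file_path_sans_ext(path), ".fdt")
    con <- file(fdt, "wb")
    writeBin(as.double(as.vector(raw$data)), con, size = 4L,
             endian = "little")
    close(con)
    data_field <- basename(fdt)
  } else {
    data_field <- raw$data
  }
  eeg <- list(
    setname = raw$subject_id,
    nbchan = nrow(raw$data),
    pnts = ncol(raw$data),
    trials = 1,
    srate = raw$fs,
    chanlocs = unname(chanlocs),
    data = data_field
  )
  header <- charToRaw(edf_pad("MATLAB 5.0 MAT-file, written by eegdem", 116))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(raw(8), con) # subsystem offset
  writeBin(c(0x00L, 0x01L), con, size = 1L) # version 0x0100 little-endian
  writeChar("IM", con, eos = NULL)
  writeBin(mat5_matrix(eeg, name = "EEG"), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

mat5_read_tag <- function(buf, pos) {
  tag <- readBin(buf[pos:(pos + 7)], "integer", 2L, size = 4L,
                 endian = "little")
  type <- tag[1]
  small <- bitwAnd(type, -65536L) != 0L # small element: length in hi bytes
  if (small) {
    nbytes <- bitwShiftR(bitwAnd(type, -65536L), 16L)
    type <- bitwAnd(type, 65535L)
    list(type = type, nbytes = nbytes, data_pos = pos + 4L,
         next_pos = pos + 8L)
  } else {
    nbytes <- tag[2]
    adv <- 8L + nbytes + pad8(nbytes)
    list(type = type, nbytes = nbytes, data_pos = pos + 8L,
         next_pos = pos + adv)
  }
}

mat5_read_numeric <- function(buf, type, pos, nbytes) {
  sz <- switch(as.character(type),
    "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
    "7" = 4L, "9" = 8L,
    stop("unsupported MAT data type ", type)
  )
  n <- nbytes %/% sz
  slice <- buf[pos:(pos + nbytes - 1L)]
  if (type %in% c(MI_SINGLE, MI_DOUBLE)) {
    readBin(slice, "double", n, size = sz, endian = "little")
  } else {
    signed <- type %in% c(MI_INT8, MI_INT16, MI_INT32)
    readBin(slice, "integer", n, size = sz, signed = signed || sz == 4L,
            endian = "little")
  }
}

mat5_read_matrix <- function(buf, pos, nbytes) {
  end <- pos + nbytes
  flags_tag <- mat5_read_tag(buf, pos)
  flags <- readBin(buf[flags_tag$data_pos:(flags_tag$data_pos + 3)],
                   "integer", 1L, size = 4L, endian = "little")
  class_id <- bitwAnd(flags, 255L)
  p <- flags_tag$next_pos
  dim_tag <- mat5_read_tag(buf, p)
  dims <- mat5_read_numeric(buf, dim_tag$type, dim_tag$data_pos,
                            dim_tag$nbytes)
  p <- dim_tag$next_pos
  name_tag <- mat5_read_tag(buf, p)
  nm <- if (name_tag$nbytes > 0) {
    rawToChar(buf[name_tag$data_pos:(name_tag$data_pos +
                                       name_tag$nbytes - 1L)])
  } else ""
  p <- name_tag$next_pos

  if (class_id == MX_STRUCT) {
    fl_tag <- mat5_read_tag(buf, p)
    p <- fl_tag$next_pos
    fn_tag <- mat5_read_tag(buf, p)
    fname_raw <- buf[fn_tag$data_pos:(fn_tag$data_pos + fn_tag$nbytes - 1L)]
    flen <- mat5_read_numeric(buf, fl_tag$type, fl_tag$data_pos,
                              fl_tag$nbytes)[1]
    nfields <- fn_tag$nbytes %/% flen
    fields <- vapply(seq_len(nfields), function(i) {
      b <- fname_raw[((i - 1L) * flen + 1L):(i * flen)]
      rawToChar(b[b != as.raw(0)])
    }, "")
    p <- fn_tag$next_pos
    n_elem <- prod(dims)
    elems <- vector("list", n_elem)
    for (e in seq_len(n_elem)) {
      el <- stats::setNames(vector("list", nfields), fields)
      for (f in fields) {
        sub <- mat5_read_tag(buf, p)
        if (sub$type != MI_MATRIX) stop("malformed MAT struct field")
        el[[f]] <- mat5_read_matrix(buf, sub$data_pos, sub$nbytes)$value
        p <- sub$next_pos
      }
      elems[[e]] <- el
    }
    value <- if (n_elem == 1L) elems[[1]] else elems
  } else if (class_id == MX_CHAR) {
    d_tag <- mat5_read_tag(buf, p)
    codes <- mat5_read_numeric(buf, d_tag$type, d_tag$data_pos,
                               d_tag$nbytes)
    value <- intToUtf8(codes[codes > 0])
  } else if (class_id %in% c(MX_DOUBLE, MX_SINGLE) ||
               class_id %in% 8:15) {
    d_tag <- mat5_read_tag(buf, p)
    v <- mat5_read_numeric(buf, d_tag$type, d_tag$data_pos, d_tag$nbytes)
    value <- if (length(dims) == 2L) {
      matrix(as.double(v), dims[1], dims[2])
    } else {
      array(as.double(v), dims)
    }
  } else {
    stop("unsupported MAT array class ", class_id)
  }
  list(name = nm, value = value, end = end)
}

#' Read an EEGLAB .set file
#'
#' Supports uncompressed MAT v5 files (the layout [write_eeglab_set()]
#' produces, and EEGLAB files saved without compression), with signal data
#' inline or in a sibling `.fdt` float32 file. Compressed MAT elements are
#' not supported.
#'
#' @param path `.set` file path.
#' @return A [raw_eeg()] object.
#' @export
read_eeglab_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 136L) stop("format error: truncated .set file ", path)
  endian <- rawToChar(buf[127:128])
  if (endian != "IM") {
    stop("format error: unsupported MAT endianness/header in ", path)
  }
  pos <- 129L
  eeg <- NULL
  while (pos + 8L <= length(buf)) {
    tag <- mat5_read_tag(buf, pos)
    if (tag$type == MI_COMPRESSED) {
      stop(
        "compressed MAT element in ", path,
        ": re-save the .set without compression"
      )
    }
    if (tag$type == MI_MATRIX) {
      m <- mat5_read_matrix(buf, tag$data_pos, tag$nbytes)
      if (is.list(m$value) && !is.null(m$value$srate)) {
        eeg <- m$value
        break
      }
    }
    pos <- tag$next_pos
  }
  if (is.null(eeg)) stop("format error: no EEG struct found in ", path)

  nbchan <- as.integer(eeg$nbchan[1])
  pnts <- as.integer(eeg$pnts[1])
  trials <- if (!is.null(eeg$trials)) as.integer(eeg$trials[1]) else 1L
  if (is.na(nbchan) || nbchan < 1L) {
    stop("format error: zero channels in ", path)
  }
  if (is.character(eeg$data)) {
    fdt <- file.path(dirname(path), eeg$data)
    if (!file.exists(fdt)) stop("missing .fdt data file: ", fdt)
    v <- readBin(fdt, "double", n = nbchan * pnts * trials, size = 4L,
                 endian = "little")
    data <- matrix(v, nrow = nbchan)
  } else {
    data <- matrix(as.double(eeg$data), nrow = nbchan)
  }
  ch <- if (!is.null(eeg$chanlocs)) {
    locs <- eeg$chanlocs
    if (!is.null(names(locs))) locs <- list(locs)
    vapply(locs, function(l) as.character(l$labels), "")
  } else {
    sprintf("ch%02d", seq_len(nbchan))
  }
  raw_eeg(
    data = data, fs = as.numeric(eeg$srate[1]), channel_names = ch,
    subject_id = if (!is.null(eeg$setname)) eeg$setname else "unknown"
  )
}
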