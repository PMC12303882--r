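# Plain EDF (European Data Format) reader/writer. EDF stores a 256-byte
# fixed header, one 256-byte header block per signal, then data records of
# 16-bit little-endian integers scaled linearly between the per-signal
# digital and physical ranges. One-second records are used on write.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = width, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(format(x, scientific = FALSE), 1, width)
  edf_pad(trimws(s), width)
}

#' Write a recording to an EDF file
#'
#' Uses one-second data records; any trailing partial second is dropped
#' (with a warning). Physical ranges are set per channel from the data, so
#' the round-trip error is bounded by the 16-bit quantization step.
#'
#' @param raw a [raw_eeg()] object.
#' @param path output path.
#' @export
write_edf <- function(raw, path) {
  stopifnot(inherits(raw, "raw_eeg"))
  fs <- raw$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_sig <- nrow(raw$data)
  n_rec <- ncol(raw$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one 1-s EDF record")
  if (n_rec * fs < ncol(raw$data)) {
    warning("dropping trailing partial second when writing EDF")
  }
  x <- raw$data[, seq_len(n_rec * fs), drop = FALSE]

  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768
  dmax <- 32767

  dig <- round(sweep(sweep(x, 1, pmin), 1, (pmax - pmin), "/") *
                 (dmax - dmin) + dmin)
  dig[dig > dmax] <- dmax
  dig[dig < dmin] <- dmin
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    edf_pad("0", 8),
    edf_pad(raw$subject_id, 80),
    edf_pad("eegdem synthetic", 80),
    edf_pad("01.01.00", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * n_sig, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(n_sig, 4)
  )
  sig_header <- paste0(
    paste(edf_pad(raw$channel_names, 16), collapse = ""),
    paste(rep(edf_pad("", 80), n_sig), collapse = ""),
    paste(rep(edf_pad("uV", 8), n_sig), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), n_sig), collapse = ""),
    paste(rep(edf_pad(dmax, 8), n_sig), collapse = ""),
    paste(rep(edf_pad("", 80), n_sig), collapse = ""),
    paste(rep(edf_pad(fs, 8), n_sig), collapse = ""),
    paste(rep(edf_pad("", 32), n_sig), collapse = "")
  )
  writeChar(paste0(header, sig_header), con, eos = NULL)
  # record-major layout: record, then signal, then sample
  arr <- array(dig, dim = c(n_sig, fs, n_rec))
  writeBin(as.integer(aperm(arr, c(2, 1, 3))), con,
           size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A [raw_eeg()] object; data are scaled to physical units.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- rawToChar(readBin(con, "raw", w))
    trimws(s)
  }
  rd(8) # version
  patient <- rd(80)
  rd(80) # recording id
  rd(8); rd(8) # date, time
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  n_sig <- suppressWarnings(as.integer(rd(4)))
  if (is.na(n_sig) || is.na(n_rec) || is.na(rec_dur) ||
      is.na(header_bytes)) {
    stop("format error: corrupt EDF header in ", path)
  }
  if (n_sig < 1L) stop("format error: zero channels in ", path)

  rdv <- function(w) vapply(seq_len(n_sig), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80) # transducer
  rdv(8)  # dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80) # prefilter
  spr <- as.integer(rdv(8))
  rdv(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr))) {
    stop("format error: corrupt EDF signal header in ", path)
  }
  if (length(unique(spr)) != 1L) {
    stop("EDF files with differing per-signal rates are not supported")
  }
  fs <- spr[1] / rec_dur

  vals <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                  signed = TRUE, endian = "little")
  if (length(vals) < n_rec * sum(spr)) {
    stop("format error: truncated EDF data in ", path)
  }
  arr <- array(vals, dim = c(spr[1], n_sig, n_rec))
  dig <- matrix(aperm(arr, c(2, 1, 3)), nrow = n_sig)
  phys <- (dig - dmin) / (dmax - dmin) * (pmax - pmin) + pmin
  raw_eeg(
    data = phys, fs = fs, channel_names = labels,
    subject_id = if (nzchar(patient)) patient else "unknown"
  )
}
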