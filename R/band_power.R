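#' Welch power spectral density estimate
#'
#' Splits the signal into overlapping tapered segments, averages the
#' squared magnitude of each segment's discrete Fourier transform, and
#' scales to a one-sided density so that the integral of the PSD over
#' frequency approximates the variance of a zero-mean signal
#' (Parseval-consistent).
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate in Hz.
#' @param seg_len_s segment length in seconds (default 2 s, giving 0.5 Hz
#'   resolution — the minimum that resolves the 0.5 Hz lower band edge).
#' @param seg_overlap fractional overlap between segments (default 0.5).
#' @param window taper: `"hann"` or `"rect"`.
#' @param demean remove each segment's mean before tapering.
#' @return Object of class `psd_estimate`: list with `freqs` (Hz) and
#'   `power` (density per Hz).
#' @export
welch_psd <- function(x, fs, seg_len_s = 2, seg_overlap = 0.5,
                      window = c("hann", "rect"), demean = TRUE) {
  window <- match.arg(window)
  n <- round(seg_len_s * fs)
  if (n < 2L) stop("segment too short")
  if (length(x) < n) {
    stop("signal shorter than one Welch segment (",
         length(x), " < ", n, " samples)")
  }
  if (seg_overlap < 0 || seg_overlap >= 1) {
    stop("'seg_overlap' must be in [0, 1)")
  }
  step <- max(1L, round(n * (1 - seg_overlap)))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  } else {
    rep(1, n)
  }
  u <- sum(w^2)
  half <- n %/% 2
  acc <- numeric(half + 1L)
  for (st in starts) {
    seg <- x[st:(st + n - 1L)]
    if (demean) seg <- seg - mean(seg)
    sp <- abs(stats::fft(seg * w))^2
    acc <- acc + sp[seq_len(half + 1L)]
  }
  pxx <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- 2:(half + if (n %% 2 == 0) 0L else 1L)
  pxx[dbl] <- 2 * pxx[dbl]
  structure(
    list(freqs = (0:half) * fs / n, power = pxx),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "psd_estimate: %d bins, %g-%g Hz (resolution %g Hz)\n",
    length(x$freqs), min(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]
  ))
  invisible(x)
}

band_bin_mask <- function(freqs, lo, hi, hi_inclusive) {
  freqs >= lo & (if (hi_inclusive) freqs <= hi else freqs < hi)
}

#' Relative band power from a PSD estimate
#'
#' Sums the PSD over the discrete bins whose centre frequency falls in the
#' band (half-open upper edge, inclusive for the scheme's final band) and
#' divides by the sum over the scheme's full analysis range.
#'
#' @param psd a [welch_psd()] result.
#' @param band band name (looked up in `scheme`).
#' @param scheme a [band_scheme()].
#' @return RBP fraction in `[0, 1]`.
#' @export
band_power_fraction <- function(psd, band, scheme = band_scheme("modified")) {
  stopifnot(inherits(psd, "psd_estimate"))
  i <- match(band, scheme$band)
  if (is.na(i)) stop("unknown band '", band, "'")
  total_mask <- psd$freqs >= attr(scheme, "total_lo") &
    psd$freqs <= attr(scheme, "total_hi")
  denom <- sum(psd$power[total_mask])
  if (denom <= 0) {
    stop("undefined RBP: zero total power in the analysis range")
  }
  num <- sum(psd$power[
    band_bin_mask(psd$freqs, scheme$lo[i], scheme$hi[i], scheme$hi_inclusive[i])
  ])
  num / denom
}

# Full per-band RBP vector for one channel's PSD.
rbp_vector <- function(psd, scheme) {
  vapply(scheme$band, band_power_fraction, 0, psd = psd, scheme = scheme)
}

#' Segment a recording into overlapping epochs
#'
#' Epochs are `length_s` seconds long and start every
#' `length_s * (1 - overlap)` seconds; trailing samples that do not fill a
#' whole epoch are dropped.
#'
#' @param raw a [raw_eeg()] object.
#' @param length_s epoch length in seconds (default 6).
#' @param overlap fractional overlap (default 0.5).
#' @return List of channels x samples matrices.
#' @export
epoch_signal <- function(raw, length_s = 6, overlap = 0.5) {
  stopifnot(inherits(raw, "raw_eeg"))
  if (length_s <= 0) stop("'length_s' must be > 0")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  len <- round(length_s * raw$fs)
  step <- round(len * (1 - overlap))
  n <- ncol(raw$data)
  if (n < len) {
    stop("recording shorter than one epoch (", n, " < ", len, " samples)")
  }
  n_ep <- (n - len) %/% step + 1L
  lapply(seq_len(n_ep), function(e) {
    st <- (e - 1L) * step + 1L
    raw$data[, st:(st + len - 1L), drop = FALSE]
  })
}

#' Channel-averaged relative band power of one epoch
#'
#' Computes the per-channel RBP vectors and returns their unweighted mean
#' over channels (not the RBP of an averaged PSD).
#'
#' @param epoch channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param scheme a [band_scheme()].
#' @param seg_len_s,seg_overlap,window Welch parameters, see
#'   [welch_psd()].
#' @return Named per-band RBP vector.
#' @export
epoch_rbp <- function(epoch, fs, scheme = band_scheme("modified"),
                      seg_len_s = 2, seg_overlap = 0.5, window = "hann") {
  if (is.null(dim(epoch))) epoch <- matrix(epoch, nrow = 1L)
  epoch <- as.matrix(epoch)
  if (nrow(epoch) < 1L) stop("epoch must have at least one channel")
  per_ch <- vapply(seq_len(nrow(epoch)), function(i) {
    rbp_vector(
      welch_psd(epoch[i, ], fs, seg_len_s, seg_overlap, window),
      scheme
    )
  }, numeric(nrow(scheme)))
  if (is.null(dim(per_ch))) per_ch <- matrix(per_ch, nrow = 1L)
  stats::setNames(rowMeans(per_ch), scheme$band)
}

#' Extract the epoch-level RBP feature matrix from labelled recordings
#'
#' Every recording is segmented into overlapping epochs; each epoch
#' becomes one row of channel-averaged RBP values, labelled with the
#' source recording's class and subject id.
#'
#' @param recordings an `eeg_dataset` (see [generate_eeg_dataset()]) or a
#'   list of labelled [raw_eeg()] objects.
#' @param scheme a [band_scheme()].
#' @param epoch_s,epoch_overlap epoching parameters (defaults 6 s, 50%).
#' @param seg_len_s,seg_overlap,window Welch parameters.
#' @return An [rbp_features()] matrix with one row per epoch.
#' @export
extract_features <- function(recordings, scheme = band_scheme("modified"),
                             epoch_s = 6, epoch_overlap = 0.5,
                             seg_len_s = 2, seg_overlap = 0.5,
                             window = "hann") {
  if (inherits(recordings, "eeg_dataset")) {
    recs <- recordings$recordings
  } else if (inherits(recordings, "raw_eeg")) {
    recs <- list(recordings)
  } else {
    recs <- recordings
  }
  rows <- list()
  labels <- character(0)
  subjects <- character(0)
  for (r in recs) {
    stopifnot(inherits(r, "raw_eeg"))
    if (is.na(r$label) || !nzchar(r$label)) {
      stop("unlabeled recording (subject ", r$subject_id, ")")
    }
    eps <- epoch_signal(r, epoch_s, epoch_overlap)
    feats <- t(vapply(
      eps, epoch_rbp, numeric(nrow(scheme)),
      fs = r$fs, scheme = scheme, seg_len_s = seg_len_s,
      seg_overlap = seg_overlap, window = window
    ))
    rows[[length(rows) + 1L]] <- feats
    labels <- c(labels, rep(r$label, length(eps)))
    subjects <- c(subjects, rep(r$subject_id, length(eps)))
  }
  rbp_features(do.call(rbind, rows), scheme$band, labels, subjects)
}
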