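#' Preprocessing configuration
#'
#' @param band_lo,band_hi Butterworth bandpass edges in Hz (defaults
#'   0.5-45).
#' @param filter_order Butterworth design order (default 4), applied
#'   forward-backward so the effective response is squared and zero-phase.
#' @param asr_window_s window length for artifact correction, seconds.
#' @param asr_cutoff flag a window when any channel's standard deviation
#'   exceeds this many multiples of that channel's robust baseline SD
#'   (median of window SDs).
#' @param ica_components components to remove: `"none"`, `"auto"` (remove
#'   components correlating > 0.8 in absolute value with the mean of the
#'   frontal channels), or an integer index vector.
#' @param frontal_channels channel names used by `"auto"` mode.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_lo = 0.5, band_hi = 45,
                              filter_order = 4, asr_window_s = 0.5,
                              asr_cutoff = 17, ica_components = "none",
                              frontal_channels = c("Fp1", "Fp2")) {
  if (band_lo <= 0 || band_hi <= band_lo) {
    stop("config error: need 0 < band_lo < band_hi")
  }
  if (asr_cutoff <= 0) stop("config error: asr_cutoff must be > 0")
  if (asr_window_s <= 0) stop("config error: asr_window_s must be > 0")
  structure(
    list(
      band_lo = band_lo, band_hi = band_hi, filter_order = filter_order,
      asr_window_s = asr_window_s, asr_cutoff = asr_cutoff,
      ica_components = ica_components, frontal_channels = frontal_channels
    ),
    class = "preprocess_config"
  )
}

# Factor a Butterworth bandpass design into second-order sections
# (conjugate pole pairs, one zero at +1 and one at -1 each). Filtering
# through the cascade keeps the recursion well conditioned even with the
# 0.5 Hz edge poles sitting close to the unit circle, where the
# direct-form order-2n recursion loses several digits.
butter_sections <- function(order, w_lo, w_hi) {
  zp <- signal::as.Zpg(signal::butter(order, c(w_lo, w_hi), type = "pass"))
  p <- zp$pole[Im(zp$pole) >= 0]
  p <- p[order(-Mod(p))]
  sections <- lapply(seq_along(p), function(i) {
    list(b = c(1, 0, -1), a = c(1, -2 * Re(p[i]), Mod(p[i])^2))
  })
  list(sections = sections, gain = Re(zp$gain))
}

sos_pass <- function(x, sos) {
  y <- x * sos$gain
  for (s in sos$sections) {
    y <- as.numeric(signal::filter(s$b, s$a, y))
  }
  y
}

# Odd-reflection padding: preserves the value and first derivative at the
# boundary, so pad kinks excite the slow low-edge poles only weakly.
reflect_pad <- function(x, padlen) {
  n <- length(x)
  c(2 * x[1] - x[(padlen + 1L):2L], x,
    2 * x[n] - x[(n - 1L):(n - padlen)])
}

# Zero-phase cascade filtering. Each pass gets fresh reflection padding of
# its own input (the second pass re-pads the already-filtered data), so a
# pad-boundary transient raised by one pass is discarded with the pad
# instead of being smeared into the data by the next pass.
sos_filtfilt <- function(x, sos, padlen) {
  n <- length(x)
  padlen <- min(n - 1L, padlen)
  y <- sos_pass(reflect_pad(x, padlen), sos)
  y <- y[(padlen + 1L):(padlen + n)]
  y <- rev(sos_pass(reflect_pad(rev(y), padlen), sos))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies an order-`filter_order` Butterworth bandpass forward and
#' backward to every channel, which squares the magnitude response and
#' cancels phase distortion so epoch alignment is preserved. The filter
#' runs as a cascade of second-order sections with reflection padding,
#' keeping the recursion numerically stable despite the near-unit-circle
#' poles a 0.5 Hz low edge implies.
#'
#' @param raw a [raw_eeg()] object.
#' @param cfg a [preprocess_config()].
#' @return Filtered [raw_eeg()], same shape.
#' @export
eeg_bandpass <- function(raw, cfg = preprocess_config()) {
  stopifnot(inherits(raw, "raw_eeg"))
  nyq <- raw$fs / 2
  if (cfg$band_hi >= nyq) {
    stop("config error: band_hi must be below the Nyquist frequency ", nyq)
  }
  sos <- butter_sections(cfg$filter_order, cfg$band_lo / nyq,
                         cfg$band_hi / nyq)
  # the slowest pole of the 0.5 Hz edge rings with a ~1 s time constant;
  # a 10 s reflected pad lets both passes settle to ~e^-12 before the data
  padlen <- as.integer(round(10 * raw$fs))
  out <- raw
  for (i in seq_len(nrow(raw$data))) {
    out$data[i, ] <- sos_filtfilt(raw$data[i, ], sos, padlen)
  }
  out
}

#' Windowed artifact-subspace correction
#'
#' The signal is tiled into non-overlapping windows of `asr_window_s`
#' seconds. A window is flagged when any channel's SD exceeds
#' `asr_cutoff` times that channel's robust baseline SD (the median of its
#' window SDs). Flagged windows are reconstructed by projecting their
#' samples onto the principal subspace of the unflagged data (components
#' kept until >= 95% variance is explained); unflagged windows are never
#' modified.
#'
#' @param raw a [raw_eeg()] object (bandpass-filtered).
#' @param cfg a [preprocess_config()].
#' @return List with `eeg` (corrected [raw_eeg()]) and `mask` (logical
#'   per-window flags).
#' @export
asr_correct <- function(raw, cfg = preprocess_config()) {
  stopifnot(inherits(raw, "raw_eeg"))
  win <- round(cfg$asr_window_s * raw$fs)
  n_win <- ncol(raw$data) %/% win
  if (n_win < 2L) stop("recording must span at least two correction windows")
  x <- raw$data[, seq_len(n_win * win), drop = FALSE]
  n_ch <- nrow(x)

  sds <- matrix(0, n_ch, n_win)
  for (i in seq_len(n_ch)) {
    m <- matrix(x[i, ], nrow = win)
    mu <- colMeans(m)
    sds[i, ] <- sqrt(colSums(m^2) / win - mu^2) * sqrt(win / (win - 1))
  }
  baseline <- apply(sds, 1, stats::median)
  flagged <- apply(sds > cfg$asr_cutoff * baseline, 2, any)
  if (all(flagged)) {
    stop("degenerate calibration: every window exceeds the artifact cutoff")
  }
  out <- raw
  if (any(flagged)) {
    clean_cols <- rep(!flagged, each = win)
    clean <- x[, clean_cols, drop = FALSE]
    mu <- rowMeans(clean)
    cc <- sweep(clean, 1, mu)
    ev <- eigen(tcrossprod(cc) / ncol(cc), symmetric = TRUE)
    k <- which(cumsum(ev$values) / sum(ev$values) >= 0.95)[1]
    v <- ev$vectors[, seq_len(k), drop = FALSE]
    for (wdx in which(flagged)) {
      cols <- ((wdx - 1L) * win + 1L):(wdx * win)
      xw <- sweep(x[, cols, drop = FALSE], 1, mu)
      out$data[, cols] <- v %*% crossprod(v, xw) + mu
    }
  }
  list(eeg = out, mask = flagged)
}

# Symmetric FastICA with tanh contrast on whitened data. Returns the
# unmixing/mixing pair so removed components can be zeroed out and the
# remainder reconstructed.
fastica_decompose <- function(x, seed = 1, max_iter = 200, tol = 1e-7) {
  n_ch <- nrow(x)
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- sweep(x, 1, mu)
  cv <- tcrossprod(xc) / n
  ev <- eigen(cv, symmetric = TRUE)
  d <- pmax(ev$values, 1e-12)
  k_whiten <- diag(1 / sqrt(d), n_ch) %*% t(ev$vectors)
  z <- k_whiten %*% xc

  set.seed(as.integer(seed))
  w <- qr.Q(qr(matrix(stats::rnorm(n_ch * n_ch), n_ch)))
  sym_decor <- function(w) {
    sw <- eigen(tcrossprod(w), symmetric = TRUE)
    sw$vectors %*% diag(1 / sqrt(pmax(sw$values, 1e-12)), n_ch) %*%
      t(sw$vectors) %*% w
  }
  w <- sym_decor(w)
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    w_new <- sym_decor(g %*% t(z) / n - diag(gp, n_ch) %*% w)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) break
  }
  unmix <- w %*% k_whiten
  list(
    sources = unmix %*% xc, unmixing = unmix, mixing = solve(unmix),
    center = mu
  )
}

#' Remove independent components from a recording
#'
#' Decomposes the (filtered) signal into independent components with
#' symmetric FastICA and reconstructs it without the selected components.
#' In `"auto"` mode, components whose absolute correlation with the mean
#' of the configured frontal channels exceeds 0.8 (the usual signature of
#' ocular activity) are removed. Removing every component yields an
#' all-zero signal; removing none reproduces the input up to numerical
#' tolerance.
#'
#' @param raw a [raw_eeg()] object with at least two channels.
#' @param cfg a [preprocess_config()]; `ica_components` selects indices,
#'   `"auto"`, or `"none"`.
#' @param seed seed for the FastICA initialization.
#' @return List with `eeg` (reconstructed [raw_eeg()]), `removed`
#'   (component indices), and `correlations` (in `"auto"` mode).
#' @export
ica_remove <- function(raw, cfg = preprocess_config(), seed = 1) {
  stopifnot(inherits(raw, "raw_eeg"))
  n_ch <- nrow(raw$data)
  if (n_ch < 2L) stop("ICA requires at least 2 channels")
  dec <- fastica_decompose(raw$data, seed = seed)
  sel <- cfg$ica_components
  cors <- NULL
  if (identical(sel, "none")) {
    removed <- integer(0)
  } else if (identical(sel, "auto")) {
    fr <- match(cfg$frontal_channels, raw$channel_names)
    fr <- fr[!is.na(fr)]
    if (!length(fr)) {
      stop("'auto' ICA removal: none of the frontal channels (",
           paste(cfg$frontal_channels, collapse = ", "),
           ") are present in the recording")
    }
    ref <- colMeans(raw$data[fr, , drop = FALSE])
    cors <- abs(apply(dec$sources, 1, stats::cor, y = ref))
    removed <- which(cors > 0.8)
  } else {
    removed <- as.integer(sel)
    if (any(removed < 1L | removed > n_ch)) {
      stop("component index out of range 1..", n_ch)
    }
  }
  keep <- setdiff(seq_len(n_ch), removed)
  out <- raw
  if (!length(keep)) {
    out$data[] <- 0
  } else {
    out$data <- dec$mixing[, keep, drop = FALSE] %*%
      dec$sources[keep, , drop = FALSE] + dec$center
  }
  list(eeg = out, removed = removed, correlations = cors)
}

#' Run the full preprocessing chain on one recording
#'
#' Bandpass, then windowed artifact correction, then ICA removal (when
#' configured).
#'
#' @param raw a [raw_eeg()] object.
#' @param cfg a [preprocess_config()].
#' @param seed seed forwarded to the ICA step.
#' @return List with `eeg` plus the artifact mask and removed-component
#'   report.
#' @export
preprocess_eeg <- function(raw, cfg = preprocess_config(), seed = 1) {
  filtered <- eeg_bandpass(raw, cfg)
  asr <- asr_correct(filtered, cfg)
  if (identical(cfg$ica_components, "none")) {
    list(eeg = asr$eeg, asr_mask = asr$mask, ica_removed = integer(0))
  } else {
    ica <- ica_remove(asr$eeg, cfg, seed = seed)
    list(eeg = ica$eeg, asr_mask = asr$mask, ica_removed = ica$removed)
  }
}
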