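# Synthetic multi-channel EEG with class-conditional band-power profiles.
# Each recording is a sum of one band-limited sinusoid per active band
# (shared amplitude across channels, independent phases per channel) plus
# Gaussian broadband noise, so the relative band power of the result is
# controlled analytically by the profile weights.

#' Standard 19-channel 10-20 montage names
#' @export
eeg_channels_1020 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
  "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2"
)

#' Class profile for the synthetic EEG generator
#'
#' Describes the spectral signature of one class: a relative amplitude per
#' frequency band, a broadband noise level, and an optional per-recording
#' multiplicative jitter of the band weights that gives recordings within a
#' class realistic heterogeneity.
#'
#' @param label class name (e.g. `"AD"`, `"FTD"`, `"HC"`).
#' @param band_weights named non-negative numeric vector; names must be
#'   bands of `scheme` and at least one weight must be positive. The
#'   sinusoid amplitude in each band is proportional to its weight.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   signal units (uV).
#' @param weight_jitter relative standard deviation of a log-normal
#'   multiplicative jitter applied independently to each band weight for
#'   each generated recording (0 = identical spectra within a class).
#'   Either a single value for all bands or a named vector giving each
#'   band its own heterogeneity (names must match `band_weights`).
#' @param scheme the active [band_scheme()].
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(label, band_weights, noise_sd = 1,
                          weight_jitter = 0,
                          scheme = band_scheme("modified")) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("'label' must be a single non-empty string")
  }
  if (is.null(names(band_weights)) || any(!nzchar(names(band_weights)))) {
    stop("'band_weights' must be a named vector")
  }
  unknown <- setdiff(names(band_weights), scheme$band)
  if (length(unknown)) {
    stop(
      "unknown band name(s) in profile: ",
      paste(unknown, collapse = ", ")
    )
  }
  if (any(band_weights < 0)) stop("band weights must be >= 0")
  if (!any(band_weights > 0)) stop("invalid profile: all band weights are zero")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (any(weight_jitter < 0)) stop("'weight_jitter' must be >= 0")
  if (length(weight_jitter) > 1) {
    if (is.null(names(weight_jitter)) ||
        !all(names(band_weights) %in% names(weight_jitter))) {
      stop("per-band 'weight_jitter' must be named for every weighted band")
    }
  }
  structure(
    list(
      label = label, band_weights = band_weights, noise_sd = noise_sd,
      weight_jitter = weight_jitter, scheme = scheme
    ),
    class = "class_profile"
  )
}

#' Default class profiles for the three study groups
#'
#' Spectral signatures loosely following resting-state EEG findings in
#' dementia: healthy controls are alpha-dominant; Alzheimer's disease shows
#' slowing (raised delta/theta, reduced alpha) with a distinct beta deficit;
#' frontotemporal dementia sits between the two with relatively preserved
#' fast activity.
#'
#' @param noise_sd broadband noise level shared by all profiles.
#' @param weight_jitter within-class spectral heterogeneity (see
#'   [class_profile()]).
#' @return Named list of three `class_profile` objects (AD, FTD, HC).
#' @export
default_profiles <- function(noise_sd = 1, weight_jitter = 0.15) {
  list(
    AD = class_profile(
      "AD",
      c(Delta = 1.6, Theta = 1.5, Alpha = 0.7, Zaeta = 0.5, Beta = 0.3,
        Gamma = 0.2),
      noise_sd = noise_sd, weight_jitter = weight_jitter
    ),
    FTD = class_profile(
      "FTD",
      c(Delta = 1.2, Theta = 1.1, Alpha = 0.9, Zaeta = 0.9, Beta = 0.7,
        Gamma = 0.3),
      noise_sd = noise_sd, weight_jitter = weight_jitter
    ),
    HC = class_profile(
      "HC",
      c(Delta = 0.8, Theta = 0.7, Alpha = 1.8, Zaeta = 0.6, Beta = 0.9,
        Gamma = 0.3),
      noise_sd = noise_sd, weight_jitter = weight_jitter
    )
  )
}

#' Generate one synthetic EEG recording
#'
#' Each active band contributes one sinusoid at a frequency drawn uniformly
#' from the middle 60% of the band (avoiding edge-bin ambiguity in band
#' power checks), with amplitude proportional to the band weight, the same
#' amplitude on every channel, and an independent random phase per channel.
#' Gaussian white noise of standard deviation `profile$noise_sd` is added.
#'
#' @param profile a [class_profile()].
#' @param duration recording length in seconds (> 0).
#' @param fs sampling rate in Hz; must exceed 90 so that the 45 Hz upper
#'   band edge stays below Nyquist.
#' @param n_channels number of channels; channel names are taken from the
#'   10-20 montage (recycled with suffixes beyond 19).
#' @param seed integer seed making the recording reproducible.
#' @param subject_id optional subject identifier.
#' @return A [raw_eeg()] object with the profile's label attached.
#' @examples
#' p <- class_profile("HC", c(Alpha = 1), noise_sd = 0)
#' r <- generate_recording(p, duration = 10, fs = 250, n_channels = 2, seed = 1)
#' @export
generate_recording <- function(profile, duration, fs = 500, n_channels = 19,
                               seed = 1, subject_id = NULL) {
  stopifnot(inherits(profile, "class_profile"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("invalid profile/request: 'duration' must be > 0")
  }
  if (fs <= 90) stop("'fs' must exceed 90 Hz (45 Hz band edge below Nyquist)")
  if (n_channels < 1) stop("'n_channels' must be >= 1")
  set.seed(as.integer(seed))

  scheme <- profile$scheme
  w <- profile$band_weights[profile$band_weights > 0]
  jit <- profile$weight_jitter
  jit <- if (length(jit) > 1) jit[names(w)] else rep(jit, length(w))
  if (any(jit > 0)) {
    w <- w * stats::rlnorm(length(w), 0, jit)
  }
  rows <- match(names(w), scheme$band)
  width <- scheme$hi[rows] - scheme$lo[rows]
  freqs <- stats::runif(
    length(w),
    scheme$lo[rows] + 0.2 * width,
    scheme$hi[rows] - 0.2 * width
  )
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  data <- matrix(0, nrow = n_channels, ncol = n)
  for (b in seq_along(w)) {
    phases <- stats::runif(n_channels, 0, 2 * pi)
    # outer product keeps shared amplitude, per-channel phase
    data <- data + w[b] * sin(outer(phases, 2 * pi * freqs[b] * tt, "+"))
  }
  if (profile$noise_sd > 0) {
    data <- data + matrix(
      stats::rnorm(n_channels * n, sd = profile$noise_sd),
      nrow = n_channels
    )
  }
  ch <- if (n_channels <= length(eeg_channels_1020)) {
    eeg_channels_1020[seq_len(n_channels)]
  } else {
    make.unique(rep(eeg_channels_1020, length.out = n_channels))
  }
  raw_eeg(
    data = data, fs = fs, channel_names = ch,
    subject_id = subject_id %||% sprintf("%s_s%d", profile$label, seed),
    label = profile$label
  )
}

#' Generate a balanced labelled synthetic dataset
#'
#' Emits exactly `n_per_class` recordings per profile, in profile order.
#' Per-recording seeds are derived deterministically from the master seed,
#' so identical `(profiles, seed)` inputs produce identical datasets while
#' distinct master seeds give distinct noise realizations.
#'
#' @param profiles list of [class_profile()] objects (one per class).
#' @param n_per_class recordings per profile (>= 1).
#' @param duration per-recording duration in seconds.
#' @param fs,n_channels see [generate_recording()].
#' @param seed master integer seed.
#' @return An object of class `eeg_dataset`: list with `recordings` (list
#'   of [raw_eeg()]), `labels`, `fs`, `n_channels`, `seed`.
#' @export
generate_eeg_dataset <- function(profiles, n_per_class, duration,
                                 fs = 500, n_channels = 19, seed = 1) {
  if (inherits(profiles, "class_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("'profiles' must contain at least one profile")
  if (!all(vapply(profiles, inherits, TRUE, "class_profile"))) {
    stop("'profiles' must be a list of class_profile objects")
  }
  if (n_per_class < 1) stop("'n_per_class' must be >= 1")
  set.seed(as.integer(seed))
  n_total <- length(profiles) * n_per_class
  sub_seeds <- sample.int(.Machine$integer.max, n_total)
  recordings <- vector("list", n_total)
  labels <- character(n_total)
  i <- 0L
  for (p in profiles) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      recordings[[i]] <- generate_recording(
        p, duration = duration, fs = fs, n_channels = n_channels,
        seed = sub_seeds[i],
        subject_id = sprintf("%s_%02d", p$label, r)
      )
      labels[i] <- p$label
    }
  }
  structure(
    list(
      recordings = recordings, labels = labels, fs = fs,
      n_channels = n_channels, seed = seed
    ),
    class = "eeg_dataset"
  )
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic EEG dataset: %d recordings (%s), %d channels @ %g Hz\n",
    length(x$recordings),
    paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
      collapse = ", "
    ),
    x$n_channels, x$fs
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
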