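test_that("Welch PSD is Parseval-consistent on white noise", {
  ints <- vapply(1:15, function(s) {
    set.seed(s)
    p <- welch_psd(rnorm(5000), fs = 500)
    sum((p$power[-1] + p$power[-length(p$power)]) / 2) * diff(p$freqs[1:2])
  }, 0)
  expect_equal(mean(ints), 1, tolerance = 0.05)
})

test_that("Welch PSD peaks at the tone frequency and handles edge cases", {
  fs <- 500
  tt <- (0:2999) / fs
  p <- welch_psd(sin(2 * pi * 10 * tt), fs)
  expect_equal(p$freqs[which.max(p$power)], 10)

  pz <- welch_psd(rep(0, 2000), fs)
  expect_true(all(pz$power == 0))

  expect_error(welch_psd(rnorm(100), fs = 500), "shorter")
})

test_that("band fractions partition unity under both schemes", {
  set.seed(2)
  x <- rnorm(3000)
  for (sname in c("modified", "standard")) {
    scheme <- band_scheme(sname)
    p <- welch_psd(x, 500)
    fr <- vapply(scheme$band, band_power_fraction, 0, psd = p,
                 scheme = scheme)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    expect_length(fr, if (sname == "modified") 6 else 5)
  }
})

test_that("band power localizes tones and matches the periodogram oracle", {
  fs <- 500
  tt <- (0:5999) / fs
  scheme <- band_scheme("modified")

  p10 <- welch_psd(sin(2 * pi * 10 * tt), fs)
  expect_gte(band_power_fraction(p10, "Alpha", scheme), 0.99)

  two <- sin(2 * pi * 2 * tt) + sin(2 * pi * 28 * tt)
  p2 <- welch_psd(two, fs)
  expect_equal(band_power_fraction(p2, "Delta", scheme), 0.5,
               tolerance = 0.02)
  expect_equal(band_power_fraction(p2, "Beta", scheme), 0.5,
               tolerance = 0.02)
  expect_lte(band_power_fraction(p2, "Zaeta", scheme), 0.02)

  po <- periodogram_rbp(two, fs, scheme)
  welch_fr <- vapply(scheme$band, band_power_fraction, 0, psd = p2,
                     scheme = scheme)
  expect_equal(unname(welch_fr), po, tolerance = 0.05)

  expect_error(band_power_fraction(welch_psd(rep(0, 2000), fs), "Alpha"),
               "zero total power")
  expect_error(band_power_fraction(p10, "Nope"), "unknown band")
})

test_that("RBP is scale invariant and monotone in in-band amplitude", {
  fs <- 250
  tt <- (0:(8 * fs - 1)) / fs
  base <- sin(2 * pi * 5 * tt) + sin(2 * pi * 27 * tt)
  scheme <- band_scheme("modified")
  fr1 <- rbp_of <- function(x) {
    p <- welch_psd(x, fs)
    vapply(scheme$band, band_power_fraction, 0, psd = p, scheme = scheme)
  }
  expect_equal(rbp_of(base), rbp_of(7.3 * base), tolerance = 1e-12)

  beta_at <- function(a) {
    rbp_of(sin(2 * pi * 5 * tt) + a * sin(2 * pi * 27 * tt))[["Beta"]]
  }
  vals <- vapply(c(0.5, 1, 2, 4), beta_at, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("epoching arithmetic matches the half-open window rule", {
  mk <- function(dur, fs = 100) {
    raw_eeg(matrix(rnorm(2 * round(dur * fs)), 2), fs, c("a", "b"))
  }
  eps <- epoch_signal(mk(60), length_s = 6, overlap = 0.5)
  expect_length(eps, 19)
  expect_true(all(vapply(eps, ncol, 0L) == 600))
  # starts at 0, 3, ..., 54 s
  r <- mk(60)
  eps2 <- epoch_signal(r, 6, 0.5)
  expect_identical(eps2[[2]][, 1], r$data[, 301])

  expect_length(epoch_signal(mk(6), 6, 0.5), 1)
  expect_length(epoch_signal(mk(8.9), 6, 0.5), 1)
  expect_error(epoch_signal(mk(3), 6, 0.5), "shorter")
})

test_that("epoch RBP averages per-channel fractions", {
  fs <- 250
  tt <- (0:(6 * fs - 1)) / fs
  alpha <- sin(2 * pi * 10 * tt)
  beta <- sin(2 * pi * 27 * tt)

  same <- rbind(alpha, alpha, alpha)
  expect_equal(epoch_rbp(same, fs), epoch_rbp(alpha, fs),
               tolerance = 1e-12)

  mixed <- rbind(alpha, beta)
  fr <- epoch_rbp(mixed, fs)
  expect_equal(fr[["Alpha"]], 0.5, tolerance = 0.01)
  expect_equal(fr[["Beta"]], 0.5, tolerance = 0.01)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
})

test_that("extract_features assembles labelled epoch rows in order", {
  profs <- list(
    class_profile("AD", c(Theta = 1, Beta = 1.8), noise_sd = 0.3),
    class_profile("HC", c(Alpha = 1.8, Beta = 0.4, Theta = 1),
                  noise_sd = 0.3)
  )
  ds <- generate_eeg_dataset(profs, n_per_class = 1, duration = 60,
                             fs = 250, n_channels = 2, seed = 6)
  fm <- extract_features(ds)
  expect_equal(nrow(fm$values), 38) # 2 recordings x 19 epochs
  expect_identical(fm$band_names, band_scheme("modified")$band)
  expect_identical(unique(fm$labels), c("AD", "HC"))
  expect_true(all(fm$values >= 0 & fm$values <= 1))
  expect_equal(rowSums(fm$values), rep(1, 38), tolerance = 1e-9)
  expect_gt(mean(fm$values[fm$labels == "AD", "Beta"]),
            mean(fm$values[fm$labels == "HC", "Beta"]))

  fm_std <- extract_features(ds, scheme = band_scheme("standard"))
  expect_equal(ncol(fm_std$values), 5)

  bad <- ds$recordings[[1]]
  bad$label <- NA_character_
  expect_error(extract_features(list(bad)), "unlabeled")
})
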