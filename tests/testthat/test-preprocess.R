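tone_rec <- function(freq, fs = 500, dur = 6, n_ch = 2, amp = 1) {
  tt <- (0:(dur * fs - 1)) / fs
  raw_eeg(
    matrix(rep(amp * sin(2 * pi * freq * tt), n_ch), nrow = n_ch,
           byrow = TRUE),
    fs, paste0("ch", seq_len(n_ch))
  )
}

test_that("bandpass rejects the stop band and passes the pass band", {
  cfg <- preprocess_config()
  hi <- tone_rec(60)
  out <- eeg_bandpass(hi, cfg)
  rms <- function(v) sqrt(mean(v^2))
  # the squared magnitude response of the order-4 Butterworth bandpass at
  # 60 Hz is 7.5% amplitude; measure away from the filter edge transients
  interior <- 750:2250
  expect_lt(rms(out$data[1, interior]), 0.09 * rms(hi$data[1, interior]))

  mid <- tone_rec(10)
  out2 <- eeg_bandpass(mid, cfg)
  expect_equal(rms(out2$data[1, ]), rms(mid$data[1, ]), tolerance = 0.05)

  z <- raw_eeg(matrix(0, 2, 1000), 500, c("a", "b"))
  expect_equal(eeg_bandpass(z, cfg)$data, z$data)

  expect_error(
    eeg_bandpass(tone_rec(10, fs = 80), cfg),
    "Nyquist"
  )
})

test_that("bandpass is linear", {
  set.seed(4)
  r <- raw_eeg(matrix(rnorm(2 * 2000), 2), 500, c("a", "b"))
  r5 <- r
  r5$data <- 5 * r$data
  f1 <- eeg_bandpass(r)
  f5 <- eeg_bandpass(r5)
  expect_equal(f5$data, 5 * f1$data, tolerance = 1e-9)
})

test_that("artifact correction flags exactly the injected burst window", {
  set.seed(7)
  fs <- 250
  n_win <- 40
  win <- fs / 2
  n <- n_win * win
  # rank-2 clean structure plus slight noise so the principal subspace is
  # well defined and low-dimensional
  tt <- (0:(n - 1)) / fs
  src <- rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 6 * tt + 1))
  mix <- matrix(c(1, 0.8, 0.5, 0.2, 0.3, 0.9, 0.7, 0.4), 4, 2)
  x <- mix %*% src + 0.02 * matrix(rnorm(4 * n), 4)
  clean <- raw_eeg(x, fs, paste0("ch", 1:4))

  cfg <- preprocess_config(asr_cutoff = 17)
  res0 <- asr_correct(clean, cfg)
  expect_false(any(res0$mask))
  expect_identical(res0$eeg$data, clean$data)

  # inject a 100x burst along a direction orthogonal to the mixing
  burst_dir <- qr.Q(qr(cbind(mix, rnorm(4), rnorm(4))))[, 3]
  target <- 13L
  cols <- ((target - 1L) * win + 1L):(target * win)
  dirty <- clean
  amp <- 100 * max(abs(x))
  dirty$data[, cols] <- dirty$data[, cols] +
    burst_dir %o% (amp * sin(2 * pi * 20 * (seq_len(win) / fs)))

  res <- asr_correct(dirty, cfg)
  expect_identical(which(res$mask), target)
  # unflagged windows untouched
  expect_identical(res$eeg$data[, -cols], dirty$data[, -cols])
  # corrected window tamed below the flagging threshold
  base_sd <- apply(matrix(clean$data[1, ], nrow = win), 2, sd)
  for (ch in 1:4) {
    m <- matrix(dirty$data[ch, ], nrow = win)
    baseline <- median(apply(m, 2, sd))
    expect_lt(sd(res$eeg$data[ch, cols]), 17 * baseline)
  }
})

test_that("Gaussian noise alone never trips the deviation cutoff", {
  set.seed(21)
  fs <- 100
  n_win <- 10000
  x <- matrix(rnorm(2 * n_win * fs / 2), 2)
  r <- raw_eeg(x, fs, c("a", "b"))
  res <- asr_correct(r, preprocess_config(asr_cutoff = 17))
  expect_equal(sum(res$mask), 0)
})

test_that("ICA removal isolates an ocular-like drift component", {
  set.seed(3)
  fs <- 250
  n <- 20 * fs
  tt <- (0:(n - 1)) / fs
  s1 <- sin(2 * pi * 10 * tt)
  s2 <- sign(sin(2 * pi * 7 * tt + 0.5))
  drift <- sin(2 * pi * 0.3 * tt) * 6
  mix <- matrix(c(1, 0.6, 0.2, 0.4, 1, 0.5, 0.9, 0.3, 1), 3, 3)
  x <- mix %*% rbind(s1, s2, drift) + 0.01 * matrix(rnorm(3 * n), 3)
  r <- raw_eeg(x, fs, c("Fp1", "Cz", "O1"))

  dec <- eegdem:::fastica_decompose(r$data, seed = 2)
  dcor <- abs(apply(dec$sources, 1, cor, y = drift))
  drift_comp <- which.max(dcor)
  expect_gt(max(dcor), 0.95)

  cfg <- preprocess_config(ica_components = drift_comp)
  out <- ica_remove(r, cfg, seed = 2)
  lowpow <- function(v) {
    sp <- abs(fft(v - mean(v)))^2
    f <- (seq_along(v) - 1) * fs / length(v)
    sum(sp[f > 0 & f < 1])
  }
  for (ch in 1:3) {
    expect_lt(lowpow(out$eeg$data[ch, ]), 0.1 * lowpow(r$data[ch, ]))
  }
})

test_that("ICA identity, annihilation, rank and error cases hold", {
  set.seed(8)
  fs <- 200
  n <- 10 * fs
  x <- matrix(rnorm(4 * n), 4) + outer(c(1, 2, 3, 4), sin((1:n) / 7))
  r <- raw_eeg(x, fs, c("Fp1", "Fp2", "Cz", "O1"))

  none <- ica_remove(r, preprocess_config(ica_components = integer(0)))
  expect_equal(none$eeg$data, r$data, tolerance = 1e-6)

  all_rm <- ica_remove(r, preprocess_config(ica_components = 1:4))
  expect_true(all(all_rm$eeg$data == 0))

  two <- ica_remove(r, preprocess_config(ica_components = c(1, 3)))
  sv <- svd(two$eeg$data - rowMeans(two$eeg$data))$d
  expect_lt(sv[3] / sv[1], 1e-6) # numerical rank <= 4 - 2

  expect_error(
    ica_remove(r, preprocess_config(ica_components = 9)),
    "out of range"
  )
  r2 <- r
  r2$channel_names <- c("C1", "C2", "C3", "C4")
  expect_error(
    ica_remove(r2, preprocess_config(ica_components = "auto")),
    "frontal"
  )
})

test_that("auto mode removes components tracking the frontal average", {
  set.seed(13)
  fs <- 250
  n <- 20 * fs
  tt <- (0:(n - 1)) / fs
  blink <- 3 * (pmax(sin(2 * pi * 0.4 * tt), 0.7) - 0.7)
  s1 <- sin(2 * pi * 11 * tt)
  s2 <- sin(2 * pi * 19 * tt + 1)
  # blink loads mostly on the frontal channels
  mix <- rbind(
    c(8, 1, 0.5),
    c(7.5, 0.8, 0.6),
    c(0.5, 1, 0.9),
    c(0.2, 0.7, 1)
  )
  x <- mix %*% rbind(blink, s1, s2) + 0.01 * matrix(rnorm(4 * n), 4)
  r <- raw_eeg(x, fs, c("Fp1", "Fp2", "Cz", "O1"))
  out <- ica_remove(r, preprocess_config(ica_components = "auto"), seed = 4)
  expect_gte(length(out$removed), 1)
  # the removed component is the blink: frontal slow power collapses
  lowpow <- function(v) {
    sp <- abs(fft(v - mean(v)))^2
    f <- (seq_along(v) - 1) * fs / length(v)
    sum(sp[f > 0 & f < 1])
  }
  expect_lt(lowpow(out$eeg$data[1, ]), 0.15 * lowpow(r$data[1, ]))
})
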