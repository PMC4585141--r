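test_that("MFCCs of digital silence are exactly zero", {
  m <- mfcc_stream(audio_signal(numeric(8000), 16000), 20, 12)
  expect_gt(nrow(m), 0)
  expect_lt(max(abs(m)), 1e-10)
  # every frame identical
  expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-12)
})

test_that("filter-bank energies match a direct triangle-weight oracle", {
  fs <- 16000; fp <- frame_params()
  sig <- audio_signal(sin(2 * pi * 1000 * (0:7999) / fs), fs)
  ps <- sourcetract:::st_power_spectrum(sig, fs, fp)
  fb <- mel_filterbank(20, fp$fft_size, fs)
  # independent evaluation of the triangle weights on the periodogram
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(0, mel(fs / 2), length.out = 22))
  freqs <- (0:(fp$fft_size / 2)) * fs / fp$fft_size
  direct <- sapply(1:20, function(i) {
    w <- pmax(0, pmin((freqs - edges[i]) / (edges[i + 1] - edges[i]),
                      (edges[i + 2] - freqs) / (edges[i + 2] - edges[i + 1])))
    colSums(w * ps)
  })
  expect_lt(max(abs(t(fb %*% ps) - direct)) / max(direct), 1e-10)
})

test_that("configured filter counts must be resolvable and consistent", {
  expect_error(mfcc_stream(audio_signal(rnorm(8000), 16000), 10, 12), "n_mfcc")
  expect_error(mel_filterbank(300, 512, 16000), "Configuration error")
})

test_that("delta is the least-squares slope of the trajectory", {
  expect_true(all(delta(matrix(5, 50, 3)) == 0))
  ramp <- matrix(seq_len(40) * 0.25, ncol = 1)
  d <- delta(ramp, half_window = 2)
  expect_equal(d[3:38, 1], rep(0.25, 36), tolerance = 1e-12)
  # direct regression-formula oracle on random data
  withr::with_seed(1, x <- matrix(rnorm(200), 50, 4))
  h <- 3
  pad <- rbind(x[rep(1, h), ], x, x[rep(50, h), ])
  oracle <- matrix(0, 50, 4)
  for (t in 1:50)
    oracle[t, ] <- sapply(1:4, function(j)
      sum((-h:h) * pad[t + h + (-h:h), j]) / sum((1:h)^2 * 2))
  expect_lt(max(abs(delta(x, half_window = 3) - oracle)), 1e-12)
})

test_that("frame energy matches the closed-form windowed sum", {
  fs <- 16000; fp <- frame_params()
  x <- sin(2 * pi * 250 * (0:3999) / fs)
  e <- frame_energy(audio_signal(x, fs), fp)
  w <- sourcetract:::hamming_window(400)
  direct <- log(sum((w * x[1:400])^2))
  expect_lt(abs(e[1] - direct), 1e-9)
  ez <- frame_energy(audio_signal(numeric(2000), fs), fp)
  expect_true(all(ez == log(1e-10)))
  expect_true(all(abs(delta(ez)) < 1e-12))
})

test_that("cepstral mean subtraction centers and is idempotent", {
  withr::with_seed(2, x <- matrix(rnorm(300), 50, 6))
  y <- cms(x)
  expect_lt(max(abs(colMeans(y))), 1e-12)
  expect_equal(cms(y), y, tolerance = 1e-14)
  expect_equal(cms(x + rep(3, each = 50)), y, tolerance = 1e-12)
  expect_true(all(cms(matrix(rnorm(6), 1, 6)) == 0))
})

test_that("feature warping is rank-based and median-centered", {
  withr::with_seed(3, x <- matrix(rnorm(400), 100, 4))
  w1 <- feature_warp(x, 31)
  # invariance under any strictly monotone per-dimension transform
  w2 <- feature_warp(exp(2 * x) + 5 * x, 31)
  expect_identical(w1, w2)
  # the median of an odd window maps to zero
  v <- seq_len(31)
  expect_lt(abs(feature_warp(matrix(v, ncol = 1), 31)[16, 1]), 1e-6)
  # long stationary input warps to an approximately normal margin
  withr::with_seed(4, long <- matrix(rnorm(800), ncol = 1) + 3)
  wl <- feature_warp(long, 301)
  skew <- mean((wl - mean(wl))^3) / sd(wl)^3
  expect_lt(abs(skew), 0.5)
  expect_error(feature_warp(matrix(1:2, 2, 1), 31), "at least 3")
})

test_that("RASTA filtering matches its difference-equation oracle", {
  withr::with_seed(5, x <- matrix(rnorm(160), 80, 2))
  y <- rasta(x, pole = 0.94)
  b <- 0.1 * c(2, 1, 0, -1, -2)
  oracle <- matrix(0, 80, 2)
  for (j in 1:2) {
    pad <- c(rep(x[1, j], 4), x[, j])
    fir <- numeric(80)
    for (t in 1:80) fir[t] <- sum(b * pad[t + 4 - 0:4])
    out <- numeric(80)
    prev <- 0
    for (t in 1:80) { out[t] <- fir[t] + 0.94 * prev; prev <- out[t] }
    oracle[, j] <- out
  }
  expect_lt(max(abs(y - oracle)), 1e-12)
  # DC rejection: constant trajectories map to zero
  expect_lt(max(abs(rasta(matrix(7, 100, 3)))[-(1:50)]), 1e-6)
})

test_that("RASTA passes syllable-rate modulation and rejects slow drift", {
  fr <- 100  # frames per second
  gain_at <- function(f_hz) {
    t <- seq_len(2000)
    y <- rasta(matrix(sin(2 * pi * f_hz * t / fr), ncol = 1))
    max(abs(y[500:2000, 1]))
  }
  g4 <- gain_at(4)
  expect_gte(g4, gain_at(0.1))
  expect_gte(g4, gain_at(30))
})

test_that("energy VAD finds speech segments and applies heuristics", {
  fs <- 16000
  withr::with_seed(6, {
    # stationary noise floor only: everything rejected
    noise <- audio_signal(rnorm(fs) * 1e-3, fs)
    expect_false(any(energy_vad(noise)))
  })
  # vowel - silence - vowel: boundaries within 50 ms
  v <- synthesize_utterance(canonical_vowel_spec(), 1, seed = 2,
                            silence_s = 0)$samples
  sig <- audio_signal(c(v[1:fs], numeric(fs), v[1:fs]), fs)
  mask <- energy_vad(sig)
  truth <- c(rep(TRUE, 100), rep(FALSE, 100), rep(TRUE, 98))
  expect_lt(mean(mask != truth[seq_along(mask)]), 0.05)  # 3 x 5 frames slack
})

test_that("isolated short bursts are removed by the duration heuristic", {
  fs <- 16000
  v <- synthesize_utterance(canonical_vowel_spec(), 1, seed = 2,
                            silence_s = 0)$samples
  x <- numeric(3 * fs)
  x[fs:(fs + 480)] <- v[1:481]               # 30 ms burst, isolated
  mask <- energy_vad(audio_signal(x, fs))
  expect_false(any(mask))
  # but a 30 ms burst right next to a long segment survives
  x2 <- numeric(3 * fs)
  x2[1:fs] <- v[1:fs]
  x2[(fs + 800):(fs + 1280)] <- v[1:481]     # 50 ms gap from the segment
  mask2 <- energy_vad(audio_signal(x2, fs))
  expect_true(any(mask2[104:112]))
})

test_that("spectral-amplitude denoising meets its three contracts", {
  clean <- canonical_vowel(1.5, 3)
  dn <- denoise(clean)
  expect_equal(length(dn), length(clean))
  snr <- 10 * log10(sum(clean$samples^2) /
                    sum((dn$samples - clean$samples)^2))
  expect_gte(snr, 30)
  withr::with_seed(7, noise <- audio_signal(rnorm(16000) * 0.05, 16000))
  expect_lte(sum(denoise(noise)$samples^2) / sum(noise$samples^2), 0.1)
  noisy <- synthesize_utterance(canonical_vowel_spec(), 1.5, snr_db = 5,
                                seed = 3)
  vr <- noisy$meta$voiced_range
  idx <- vr[1]:vr[2]
  ref <- clean$samples[idx]
  segsnr <- function(x) 10 * log10(sum(ref^2) / sum((x - ref)^2))
  expect_gte(segsnr(denoise(noisy)$samples[idx]) -
             segsnr(noisy$samples[idx]), 3)
})
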