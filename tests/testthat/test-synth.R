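pulse_onsets <- function(sig) {
  # pulses end in a strong negative spike; count minima under half the
  # global extreme
  x <- sig$samples
  thr <- 0.5 * min(x)
  idx <- which(x < thr)
  idx[c(TRUE, diff(idx) > 4)]
}

test_that("pulse train has one pulse per fundamental period", {
  tr <- lf_pulse_train(120, jitter = 0, shimmer = 0, duration = 1,
                       sample_rate = 16000, seed = 1)
  on <- pulse_onsets(tr)
  expect_true(abs(length(on) - 120) <= 1)
  # jitter-free cycles are identical, so inter-pulse intervals are equal
  expect_true(all(diff(diff(on)) == 0))
})

test_that("jitter-free pulse train is exactly periodic", {
  tr <- lf_pulse_train(120, jitter = 0, shimmer = 0, duration = 1,
                       sample_rate = 16000, seed = 1)
  ac <- stats::acf(tr$samples, lag.max = 200, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[100:200]) + 99, round(16000 / 120))
})

test_that("pulse train degenerate and invalid inputs", {
  expect_equal(length(lf_pulse_train(120, duration = 0)), 0L)
  expect_error(lf_pulse_train(120, lf_shape = c(oq = 0.95, rq = 0.05)),
               "oq")
  expect_error(lf_pulse_train(10, duration = 1), "f0_contour")
})

test_that("tract filter places resonances at the formant centers", {
  fm <- cbind(c(500, 1500, 2500), c(60, 90, 120))
  a <- make_tract_filter(fm, 16000)
  grid <- seq(50, 4000, by = 1)
  H <- 1 / Mod(exp(-2i * pi * outer(grid / 16000, seq_along(a) - 1)) %*% a)
  peaks <- grid[which(diff(sign(diff(H))) == -2) + 1L]
  expect_equal(length(peaks), 3L)
  expect_true(all(abs(peaks - fm[, 1]) <= 10))
})

test_that("tract filter is stable and empty formants give identity", {
  expect_identical(make_tract_filter(NULL, 16000), 1)
  for (g in c("male", "female")) {
    a <- make_tract_filter(default_formants(g), 16000)
    expect_lt(max(Mod(polyroot(rev(a)))), 1)
  }
  expect_error(make_tract_filter(cbind(9000, 100), 16000), "Nyquist")
})

test_that("utterance synthesis is a pure function of (spec, seed)", {
  sp <- speaker_spec("a", "male", 120)
  s1 <- synthesize_utterance(sp, 0.7, snr_db = 20, seed = 9)
  s2 <- synthesize_utterance(sp, 0.7, snr_db = 20, seed = 9)
  expect_identical(s1$samples, s2$samples)
  s3 <- synthesize_utterance(sp, 0.7, snr_db = 20, seed = 10)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("noiseless synthesis keeps the silence padding at digital zero", {
  sp <- speaker_spec("a", "female", 210)
  s <- synthesize_utterance(sp, 0.5, snr_db = NULL, seed = 4)
  pad <- floor(0.15 * 16000)
  expect_true(all(s$samples[seq_len(pad - 1L)] == 0))
})

test_that("synthesis closes the loop with the F0 estimator", {
  sp <- speaker_spec("a", "male", 120, f0_sd = 0, jitter = 0, shimmer = 0)
  s <- synthesize_utterance(sp, 1.5, seed = 5)
  f0 <- estimate_f0(s, f0_range = c(60, 250))
  expect_lt(abs(median(f0[f0 > 0]) - 120), 2)
})

test_that("corpus generation writes consistent manifest and files", {
  dir <- withr::local_tempdir()
  man <- generate_corpus(dir, n_speakers_per_gender = 2,
                         utterances_per_speaker = 5, duration_mean = 1.6,
                         duration_sd = 0.1,
                         split_counts = c(background = 1, dev = 1, eval = 0),
                         enroll_per_speaker = 2, seed = 3)
  expect_equal(nrow(man), 2 * 2 * 5)
  expect_true(all(file.exists(man$path)))
  expect_equal(anyDuplicated(man$utt_id), 0L)
  counts <- table(man$gender)
  expect_true(all(counts == 10))
  # manifest round trip through delimited text
  path <- file.path(dir, "manifest.tsv")
  write_manifest(man, path)
  man2 <- read_manifest(path)
  expect_equal(man2$utt_id, man$utt_id)
  expect_equal(man2$duration, man$duration)
})

test_that("corpus generation is deterministic given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_corpus(d1, 2, 2, 1.6, 0.1,
                        split_counts = c(background = 1, dev = 1, eval = 0),
                        enroll_per_speaker = 1, seed = 8)
  m2 <- generate_corpus(d2, 2, 2, 1.6, 0.1,
                        split_counts = c(background = 1, dev = 1, eval = 0),
                        enroll_per_speaker = 1, seed = 8)
  expect_equal(m1$seed, m2$seed)
  for (i in seq_len(nrow(m1)))
    expect_identical(read_wav(m1$path[i])$samples,
                     read_wav(m2$path[i])$samples)
})

test_that("different speakers have different long-term spectra", {
  sp <- sample_speakers(2, "male", seed = 21)
  s1 <- synthesize_utterance(sp[[1]], 1, seed = 5)
  s2 <- synthesize_utterance(sp[[2]], 1, seed = 5)
  p1 <- sourcetract:::st_welch(s1$samples, 16000, 512)$psd
  p2 <- sourcetract:::st_welch(s2$samples, 16000, 512)$psd
  expect_gt(sqrt(sum((10 * log10(p1 + 1e-300) -
                      10 * log10(p2 + 1e-300))^2)), 0)
})

test_that("gender populations have disjoint f0 ranges", {
  m <- sample_speakers(20, "male", seed = 2)
  f <- sample_speakers(20, "female", seed = 2)
  expect_lt(max(vapply(m, `[[`, 0, "f0_mean")),
            min(vapply(f, `[[`, 0, "f0_mean")))
})

test_that("split plans leaving speakers without data are rejected", {
  dir <- withr::local_tempdir()
  expect_error(
    generate_corpus(dir, 2, 3, enroll_per_speaker = 3,
                    split_counts = c(background = 1, dev = 1, eval = 0),
                    seed = 1),
    "Configuration error")
  expect_error(speaker_spec("x", "male", 120, jitter = 0.5), "jitter")
  expect_error(
    speaker_spec("x", "male", 120,
                 formants = cbind(c(1500, 500), c(60, 60))),
    "increasing")
})
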