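#' Single-channel spectral-amplitude denoising
#'
#' MMSE short-time spectral-amplitude estimator with decision-directed
#' a-priori SNR tracking (the Ephraim-Malah gain rule). The noise power
#' spectrum is estimated from the lowest-energy analysis frames of the
#' utterance; the per-bin gain is applied in an overlap-add STFT
#' (periodic Hann, 50% overlap), so the output has the input's length.
#'
#' @param signal An `audio_signal`.
#' @param nfft STFT window / FFT size in samples.
#' @param alpha_dd Decision-directed smoothing constant.
#' @param xi_min A-priori SNR floor (linear; -18 dB default).
#' @param noise_frac Fraction of lowest-energy frames used for the noise
#'   estimate.
#' @return A denoised `audio_signal` of the same length.
#' @export
denoise <- function(signal, nfft = 512L, alpha_dd = 0.98,
                    xi_min = 10^(-18 / 10), noise_frac = 0.1) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  n <- length(x)
  if (n == 0L) return(signal)
  hop <- nfft %/% 2L
  w <- hann_periodic(nfft)
  xp <- c(numeric(hop), x, numeric(nfft))
  starts <- seq.int(1L, length(xp) - nfft + 1L, by = hop)
  frames <- matrix(xp[outer(seq_len(nfft) - 1L, starts, `+`)], nrow = nfft)
  X <- mvfft(frames * w)
  half <- seq_len(nfft %/% 2 + 1L)
  P <- Mod(X[half, , drop = FALSE])^2

  n_noise <- max(2L, ceiling(ncol(P) * noise_frac))
  quietest <- order(colSums(P))[seq_len(min(n_noise, ncol(P)))]
  noise_psd <- rowMeans(P[, quietest, drop = FALSE])
  # smooth across frequency: few quiet frames leave per-bin estimates
  # noisy, and underestimated bins lock the decision-directed loop into
  # a high-gain fixed point
  ks <- 9L
  pad2 <- c(rep(noise_psd[1L], ks %/% 2), noise_psd,
            rep(noise_psd[length(noise_psd)], ks %/% 2))
  noise_psd <- as.double(stats::filter(pad2, rep(1 / ks, ks),
                                       sides = 2L))[(ks %/% 2 + 1L):
                                                    (ks %/% 2 + length(noise_psd))]
  noise_psd <- pmax(noise_psd, 1e-10 * mean(P) + 1e-300)

  gain_mmse <- function(xi, gamma) {
    nu <- pmin(xi * gamma / (1 + xi), 700)
    g <- sqrt(pi * nu) / (2 * pmax(gamma, 1e-12)) *
      ((1 + nu) * besselI(nu / 2, 0, expon.scaled = TRUE) +
       nu * besselI(nu / 2, 1, expon.scaled = TRUE))
    big <- nu >= 700
    if (any(big)) g[big] <- (xi / (1 + xi))[big]
    pmin(g, 1.5)
  }

  A_prev <- sqrt(pmax(P[, 1L], 0))
  G <- matrix(0, nrow(P), ncol(P))
  for (t in seq_len(ncol(P))) {
    gamma <- pmin(P[, t] / noise_psd, 1e6)
    xi <- alpha_dd * A_prev^2 / noise_psd +
      (1 - alpha_dd) * pmax(gamma - 1, 0)
    xi <- pmin(pmax(xi, xi_min), 1e6)
    g <- gain_mmse(xi, gamma)
    G[, t] <- g
    A_prev <- g * sqrt(P[, t])
  }
  Gfull <- rbind(G, G[rev(seq.int(2L, nfft %/% 2)), , drop = FALSE])
  Y <- X * Gfull
  y_frames <- Re(mvfft(Y, inverse = TRUE)) / nfft
  out <- numeric(length(xp))
  for (t in seq_along(starts)) {
    idx <- starts[t]:(starts[t] + nfft - 1L)
    out[idx] <- out[idx] + y_frames[, t]
  }
  audio_signal(out[(hop + 1L):(hop + n)], signal$sample_rate,
               meta = c(signal$meta, list(denoised = TRUE)))
}

#' Energy-based adaptive voice activity detection
#'
#' Frames are flagged as speech when their log-energy exceeds an
#' adaptive, percentile-based threshold over the utterance; duration
#' heuristics then drop short isolated speech islands (unless close to a
#' longer segment) and bridge short silences between segments.
#'
#' @param signal An `audio_signal`.
#' @param fp [frame_params()].
#' @param threshold_quantile Low quantile of the frame log-energies used
#'   as the adaptive noise-floor estimate.
#' @param offset_db Offset above the noise floor, dB.
#' @param min_speech_ms Minimum duration of an isolated speech island.
#' @param min_sil_ms Silences shorter than this between speech segments
#'   are bridged.
#' @param gap_ms Islands closer than this to a long segment are kept.
#' @return Logical vector, one flag per frame.
#' @export
energy_vad <- function(signal, fp = frame_params(),
                       threshold_quantile = 0.02, offset_db = 6,
                       min_speech_ms = 100, min_sil_ms = 200, gap_ms = 100) {
  e <- frame_energy(signal, fp)
  if (length(e) == 0L) return(logical(0))
  thr <- quantile(e, threshold_quantile, names = FALSE) +
    offset_db * log(10) / 10
  speech <- e > thr
  ms_per_frame <- fp$frame_shift_ms
  min_speech <- ceiling(min_speech_ms / ms_per_frame)
  min_sil <- ceiling(min_sil_ms / ms_per_frame)
  gap <- ceiling(gap_ms / ms_per_frame)

  r <- rle(speech)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long_runs <- which(r$values & r$lengths >= min_speech)
  if (length(long_runs) == 0L) return(rep(FALSE, length(e)))
  # drop short islands unless within gap of a long segment
  for (i in which(r$values & r$lengths < min_speech)) {
    near <- any(vapply(long_runs, function(j) {
      min(abs(c(starts[i] - ends[j], starts[j] - ends[i]))) <= gap
    }, logical(1)))
    if (!near) speech[starts[i]:ends[i]] <- FALSE
  }
  # bridge short silences between remaining speech segments
  r2 <- rle(speech)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  for (i in seq_along(r2$values)) {
    if (!r2$values[i] && i > 1L && i < length(r2$values) &&
        r2$lengths[i] < min_sil)
      speech[starts2[i]:ends2[i]] <- TRUE
  }
  speech
}
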