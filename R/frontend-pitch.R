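#' Fundamental frequency estimation (cumulative-mean-normalized
#' difference)
#'
#' Per frame: the squared difference function over candidate lags,
#' normalised by its cumulative mean; the first dip under an absolute
#' threshold is refined by parabolic interpolation. Frames without a dip
#' under the threshold are unvoiced (0).
#'
#' @param signal An `audio_signal`.
#' @param fp [frame_params()] (the shift defines the F0 frame rate; the
#'   integration window is 25 ms).
#' @param f0_range Search range `c(fmin, fmax)` in Hz, inside
#'   (20, `fs`/4).
#' @param threshold Absolute threshold on the normalised difference.
#' @return Numeric vector of F0 per frame, Hz; 0 = unvoiced.
#' @export
estimate_f0 <- function(signal, fp = frame_params(),
                        f0_range = c(60, 400), threshold = 0.1) {
  stopifnot(inherits(signal, "audio_signal"))
  fs <- signal$sample_rate
  if (f0_range[1L] <= 20 || f0_range[2L] >= fs / 4 ||
      f0_range[1L] >= f0_range[2L])
    abort("`f0_range` must lie within (20, sample_rate / 4).")
  d <- fp_samples(fp, fs)
  W <- round(0.025 * fs)
  tau_min <- max(2L, floor(fs / f0_range[2L]))
  tau_max <- ceiling(fs / f0_range[1L])
  need <- W + tau_max
  x <- signal$samples
  n_frames <- max(0L, floor((length(x) - d$len) / d$hop) + 1L)
  if (n_frames == 0L) return(numeric(0))
  x <- c(x, numeric(need))
  nfft <- next_pow2(need + tau_max)
  out <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    seg <- x[((t - 1L) * d$hop + 1L):((t - 1L) * d$hop + need)]
    seg <- seg - mean(seg)
    # difference function d(tau) = sum_{j=1..W} (x_j - x_{j+tau})^2
    c2 <- cumsum(seg^2)
    e0 <- c2[W]
    e_tau <- c2[W + 1:tau_max] - c2[1:tau_max]
    X <- fft(c(seg, numeric(nfft - need)))
    Xw <- fft(c(seg[1:W], numeric(nfft - W)))
    cc <- Re(fft(X * Conj(Xw), inverse = TRUE))[1:nfft] / nfft
    dfun <- e0 + e_tau - 2 * cc[2:(tau_max + 1L)]
    dfun <- pmax(dfun, 0)
    cmean <- cumsum(dfun) / seq_len(tau_max)
    cmndf <- c(1, (dfun / pmax(cmean, 1e-300))[-1L])
    cand <- which(cmndf[tau_min:tau_max] < threshold)
    if (length(cand) == 0L) next
    tau <- tau_min - 1L + cand[1L]
    # extend to the local minimum of the dip
    while (tau < tau_max && cmndf[tau + 1L] < cmndf[tau]) tau <- tau + 1L
    dlt <- 0
    if (tau > 1L && tau < tau_max) {
      y <- cmndf[(tau - 1L):(tau + 1L)]
      den <- y[1L] - 2 * y[2L] + y[3L]
      if (abs(den) > 1e-12) dlt <- max(-0.5, min(0.5, 0.5 * (y[1L] - y[3L]) / den))
    }
    out[t] <- fs / (tau + dlt)
  }
  out
}

#' Third-formant estimation from all-pole spectral fits
#'
#' Per voiced frame: an autocorrelation LPC fit; resonances are the
#' complex pole pairs with bandwidth under a cutoff, sorted by
#' frequency; F3 is the third such resonance, or 0 when fewer than three
#' qualify.
#'
#' @param signal An `audio_signal`.
#' @param fp [frame_params()].
#' @param lpc_order All-pole model order (>= 8).
#' @param bw_cutoff Maximum resonance bandwidth, Hz.
#' @param voiced Optional logical per-frame voicing mask; by default
#'   frames with log-energy 10 dB above the utterance's noise floor
#'   (2nd-percentile frame energy) are analysed.
#' @return Numeric vector of F3 per frame, Hz; 0 = undefined.
#' @export
estimate_f3 <- function(signal, fp = frame_params(), lpc_order = 14,
                        bw_cutoff = 400, voiced = NULL) {
  if (lpc_order < 8) abort("`lpc_order` must be >= 8.")
  stopifnot(inherits(signal, "audio_signal"))
  fs <- signal$sample_rate
  d <- fp_samples(fp, fs)
  fr <- st_frame_matrix(signal$samples, d$len, d$hop)
  n_frames <- ncol(fr)
  if (n_frames == 0L) return(numeric(0))
  if (is.null(voiced)) {
    e <- frame_energy(signal, fp)
    voiced <- e > quantile(e, 0.02, names = FALSE) + log(10)
  }
  w <- fp_window(fp, d$len)
  out <- numeric(n_frames)
  for (t in which(voiced)) {
    seg <- (fr[, t] - mean(fr[, t])) * w
    r <- st_autocorr(seg, lpc_order)
    if (r[1L] <= 0) next
    a <- st_levinson(r, lpc_order)$a
    rt <- polyroot(rev(a))
    rt <- rt[Im(rt) > 1e-6]
    freq <- Arg(rt) * fs / (2 * pi)
    bw <- -log(pmin(Mod(rt), 0.999999)) * fs / pi
    keep <- freq > 150 & freq < 0.47 * fs & bw < bw_cutoff
    f_res <- sort(freq[keep])
    if (length(f_res) >= 3L) out[t] <- f_res[3L]
  }
  out
}
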