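#' Short-time analysis parameters
#'
#' @param frame_len_ms Frame length, ms (default 25).
#' @param frame_shift_ms Frame shift, ms (default 10).
#' @param window Taper: `"hamming"` or `"hann"`.
#' @param fft_size FFT size in samples (>= frame samples at the intended
#'   sample rate).
#' @return An object of class `frame_params`.
#' @export
frame_params <- function(frame_len_ms = 25, frame_shift_ms = 10,
                         window = c("hamming", "hann"), fft_size = 512) {
  window <- match.arg(window)
  if (frame_shift_ms <= 0 || frame_len_ms < frame_shift_ms)
    abort("Need `frame_len_ms` >= `frame_shift_ms` > 0.")
  structure(list(frame_len_ms = frame_len_ms, frame_shift_ms = frame_shift_ms,
                 window = window, fft_size = as.integer(fft_size)),
            class = "frame_params")
}

fp_samples <- function(fp, fs) {
  list(len = round(fp$frame_len_ms * fs / 1000),
       hop = round(fp$frame_shift_ms * fs / 1000))
}

fp_window <- function(fp, len) {
  switch(fp$window, hamming = hamming_window(len), hann = hann_periodic(len))
}

# Windowed short-time power spectrum: (fft_size/2 + 1) x n_frames.
st_power_spectrum <- function(x, fs, fp) {
  d <- fp_samples(fp, fs)
  if (fp$fft_size < d$len) abort("`fft_size` is smaller than the frame.")
  fr <- st_frame_matrix(as_samples(x), d$len, d$hop)
  if (ncol(fr) == 0L)
    return(matrix(numeric(0), fp$fft_size %/% 2 + 1L, 0L))
  fr <- fr * fp_window(fp, d$len)
  pad <- matrix(0, fp$fft_size - d$len, ncol(fr))
  X <- mvfft(rbind(fr, pad))
  Mod(X[seq_len(fp$fft_size %/% 2 + 1L), , drop = FALSE])^2
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filter bank
#'
#' HTK-style triangular filters, equally spaced on the mel scale from 0
#' to `fs`/2, evaluated on the FFT bin grid.
#'
#' @param n_filters Number of filters.
#' @param fft_size FFT size.
#' @param fs Sample rate, Hz.
#' @return Matrix `n_filters` x (`fft_size`/2 + 1) of triangle weights.
#' @export
mel_filterbank <- function(n_filters, fft_size, fs) {
  n_bins <- fft_size %/% 2 + 1L
  edges <- mel_to_hz(seq(0, hz_to_mel(fs / 2), length.out = n_filters + 2L))
  freqs <- (seq_len(n_bins) - 1L) * fs / fft_size
  fb <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; ce <- edges[i + 1L]; hi <- edges[i + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(fb > 0) < 1L))
    abort("Configuration error: more filters than the FFT resolves.")
  fb
}

dct2_matrix <- function(n_out, n_in) {
  # orthonormal DCT-II rows 1..n_out (the 0th, constant row excluded)
  stopifnot(n_out < n_in)
  m <- outer(seq_len(n_out), (seq_len(n_in) - 0.5),
             function(k, j) cos(pi * k * j / n_in))
  m * sqrt(2 / n_in)
}

#' MFCC stream
#'
#' Windowed short-time power spectrum, triangular mel filter bank with a
#' floor applied before the log, orthonormal type-II cosine transform,
#' first `n_mfcc` coefficients (the 0th excluded; frame energy is carried
#' separately).
#'
#' @param signal `audio_signal` (or numeric at 16 kHz).
#' @param n_filters Number of mel filters.
#' @param n_mfcc Number of cepstral coefficients (< `n_filters`).
#' @param fp [frame_params()].
#' @param log_floor Floor applied to filter-bank energies before log.
#' @return Matrix frames x `n_mfcc`.
#' @export
mfcc_stream <- function(signal, n_filters, n_mfcc, fp = frame_params(),
                        log_floor = 1e-10) {
  if (n_mfcc >= n_filters) abort("`n_mfcc` must be < `n_filters`.")
  fs <- if (inherits(signal, "audio_signal")) signal$sample_rate else 16000
  ps <- st_power_spectrum(signal, fs, fp)
  fb <- mel_filterbank(n_filters, fp$fft_size, fs)
  fbe <- log(pmax(fb %*% ps, log_floor))
  t(dct2_matrix(n_mfcc, n_filters) %*% fbe)
}

#' Temporal regression (delta) coefficients
#'
#' Least-squares linear-regression slope of each feature trajectory over
#' a window of +/- `half_window` frames, edge frames replicated.
#'
#' @param features Matrix frames x dims (or vector).
#' @param half_window Regression half-window in frames (>= 1).
#' @return Same shape as `features`.
#' @export
delta <- function(features, half_window = 2) {
  if (half_window < 1) abort("`half_window` must be >= 1.")
  vec <- is.null(dim(features))
  x <- if (vec) matrix(features, ncol = 1L) else features
  n <- nrow(x)
  if (n == 0L) return(features)
  h <- half_window
  pad <- rbind(x[rep(1L, h), , drop = FALSE], x,
               x[rep(n, h), , drop = FALSE])
  num <- 0
  for (j in seq_len(h))
    num <- num + j * (pad[(1L + h + j):(n + h + j), , drop = FALSE] -
                      pad[(1L + h - j):(n + h - j), , drop = FALSE])
  out <- num / (2 * sum(seq_len(h)^2))
  if (vec) drop(out) else out
}

#' Frame log-energy
#'
#' Log of the window-weighted sample energy per frame, floored.
#'
#' @inheritParams mfcc_stream
#' @param floor Energy floor before the log.
#' @return Numeric vector, one value per frame.
#' @export
frame_energy <- function(signal, fp = frame_params(), floor = 1e-10) {
  fs <- if (inherits(signal, "audio_signal")) signal$sample_rate else 16000
  d <- fp_samples(fp, fs)
  fr <- st_frame_matrix(as_samples(signal), d$len, d$hop)
  if (ncol(fr) == 0L) return(numeric(0))
  w <- fp_window(fp, d$len)
  log(pmax(colSums((fr * w)^2), floor))
}
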