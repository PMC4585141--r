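# Shared spectral utilities: Welch averaging, Levinson-Durbin, envelope
# and harmonic peak picking. Internal.

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Welch power spectral density, one-sided. Returns list(freq, psd).
st_welch <- function(x, fs, window = 512L, overlap = 0.5, nfft = NULL) {
  x <- as.double(x)
  n <- length(x)
  window <- min(window, n)
  nfft <- nfft %||% next_pow2(window)
  w <- hann_periodic(window)
  hop <- max(1L, floor(window * (1 - overlap)))
  starts <- seq.int(1L, max(1L, n - window + 1L), by = hop)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + window - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(c(seg, numeric(nfft - window)))
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * sum(w^2) * fs)
  half <- seq_len(nfft %/% 2 + 1L)
  list(freq = (half - 1L) * fs / nfft, psd = psd[half])
}

# Levinson-Durbin on an autocorrelation sequence r[1] = lag 0.
# Returns list(a = c(1, a1..ap), k = reflection coefficients, err).
st_levinson <- function(r, order) {
  a <- 1
  e <- r[1L]
  k <- numeric(order)
  for (m in seq_len(order)) {
    if (e <= 0) { k[m:order] <- 0; break }
    acc <- r[m + 1L]
    if (m > 1L) acc <- acc + sum(a[2:m] * r[m:2])
    km <- -acc / e
    k[m] <- km
    a <- c(a, 0) + km * c(0, rev(a))
    e <- e * (1 - km^2)
  }
  if (length(a) < order + 1L) a <- c(a, numeric(order + 1L - length(a)))
  list(a = a, k = k, err = e)
}

# Autocorrelation via FFT (biased estimator), lags 0..maxlag.
st_autocorr <- function(x, maxlag) {
  n <- length(x)
  nfft <- next_pow2(2L * n)
  X <- fft(c(x, numeric(nfft - n)))
  ac <- Re(fft(Mod(X)^2, inverse = TRUE)) / nfft / n
  ac[seq_len(maxlag + 1L)]
}

# Smoothed spectral-envelope peaks: Welch log-PSD, Gaussian smoothing
# wide enough to bridge the harmonic comb, local maxima refined by
# parabolic interpolation, returned ascending in frequency.
envelope_peaks <- function(x, fs, n_peaks = 3, smooth_hz = 220,
                           window = 512L, fmin = 250, fmax = 3400) {
  if (length(x) < window) window <- next_pow2(length(x)) / 2
  ps <- st_welch(x, fs, window = window)
  df <- ps$freq[2L]
  lv <- 10 * log10(ps$psd + 1e-300)
  gsmooth <- function(v, fwhm_hz) {
    s <- fwhm_hz / df / 2.355
    half <- ceiling(3 * s)
    kern <- dnorm(-half:half, sd = s)
    kern <- kern / sum(kern)
    pad <- c(rep(v[1L], half), v, rep(v[length(v)], half))
    as.double(stats::filter(pad, kern, sides = 2L))[(half + 1L):
                                                    (half + length(v))]
  }
  # fine envelope minus a coarse baseline: removes the overall spectral
  # tilt so shallow resonance bumps survive as local maxima
  sm <- gsmooth(lv, smooth_hz) - gsmooth(lv, 6 * smooth_hz)
  pk <- which(diff(sign(diff(sm))) == -2) + 1L
  pk <- pk[ps$freq[pk] >= fmin & ps$freq[pk] <= fmax]
  refine <- vapply(pk, function(i) {
    y <- sm[(i - 1L):(i + 1L)]
    den <- y[1L] - 2 * y[2L] + y[3L]
    d <- if (abs(den) > 1e-12) max(-0.5, min(0.5, 0.5 * (y[1L] - y[3L]) / den))
         else 0
    (i - 1L + d) * df
  }, numeric(1))
  head(refine, n_peaks)
}

# Locate spectral peaks near k * f0 via high-resolution Welch +
# parabolic interpolation. Returns measured frequencies.
spectrum_harmonic_peaks <- function(x, fs, f0, n_harmonics = 5) {
  window <- min(next_pow2(length(x)), 8192L)
  ps <- st_welch(x, fs, window = window, nfft = 2L * window)
  df <- ps$freq[2L]
  vapply(seq_len(n_harmonics), function(k) {
    target <- k * f0
    lo <- max(2L, floor((target - 0.45 * f0) / df))
    hi <- min(length(ps$psd) - 1L, ceiling((target + 0.45 * f0) / df))
    i <- lo - 1L + which.max(ps$psd[lo:hi])
    # parabolic interpolation on log power
    y <- log(ps$psd[(i - 1L):(i + 1L)] + 1e-300)
    denom <- y[1L] - 2 * y[2L] + y[3L]
    delta <- if (abs(denom) > 1e-12) 0.5 * (y[1L] - y[3L]) / denom else 0
    (i - 1L + max(-0.5, min(0.5, delta))) * df
  }, numeric(1))
}

# Harmonic comb contrast: mean log-power at harmonics minus mean
# log-power at inter-harmonic troughs, in dB. Positive = harmonic.
comb_contrast <- function(x, fs, f0, n_harmonics = 5) {
  window <- min(next_pow2(length(x)), 8192L)
  ps <- st_welch(x, fs, window = window)
  df <- ps$freq[2L]
  at <- function(f) {
    i <- pmax(1L, pmin(length(ps$psd), round(f / df) + 1L))
    10 * log10(ps$psd[i] + 1e-300)
  }
  k <- seq_len(n_harmonics)
  mean(at(k * f0)) - mean(at((k + 0.5) * f0))
}

# Frame a signal into a matrix (frame_len x n_frames), no padding.
st_frame_matrix <- function(x, frame_len, hop) {
  n <- length(x)
  if (n < frame_len) return(matrix(numeric(0), frame_len, 0L))
  starts <- seq.int(1L, n - frame_len + 1L, by = hop)
  matrix(x[outer(seq_len(frame_len) - 1L, starts, `+`)],
         nrow = frame_len)
}
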