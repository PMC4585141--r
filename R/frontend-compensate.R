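#' Cepstral mean subtraction
#'
#' Subtracts the per-dimension mean over the utterance, removing
#' stationary channel effects.
#'
#' @param features Matrix frames x dims (or vector).
#' @return Same shape, zero-mean per dimension.
#' @export
cms <- function(features) {
  vec <- is.null(dim(features))
  x <- if (vec) matrix(features, ncol = 1L) else features
  if (nrow(x) == 0L) return(features)
  out <- sweep(x, 2L, colMeans(x))
  if (vec) drop(out) else out
}

#' Feature warping to a standard normal target
#'
#' Per dimension and per sliding window centered on each frame, the rank
#' of the center value is mapped through the inverse standard-normal
#' distribution function via `(rank - 0.5) / N`. Windows are truncated
#' near the utterance edges.
#'
#' @param features Matrix frames x dims (or vector).
#' @param window_frames Window length in frames (default 301, i.e. 3 s
#'   at a 10 ms shift).
#' @return Warped features, same shape.
#' @export
feature_warp <- function(features, window_frames = 301) {
  vec <- is.null(dim(features))
  x <- if (vec) matrix(features, ncol = 1L) else features
  n <- nrow(x)
  if (n == 0L) return(features)
  if (min(n, window_frames) < 3L)
    abort("Feature warping needs a window of at least 3 frames.")
  h <- (min(window_frames, n) - 1L) %/% 2L
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    for (i in seq_len(n)) {
      lo <- max(1L, i - h); hi <- min(n, i + h)
      w <- col[lo:hi]
      rk <- sum(w < col[i]) + (sum(w == col[i]) + 1) / 2   # midrank
      out[i, j] <- qnorm((rk - 0.5) / length(w))
    }
  }
  if (vec) drop(out) else out
}

#' RASTA temporal filtering
#'
#' Band-pass IIR filtering of each feature trajectory with the standard
#' transfer function: a 5-tap ramp-difference numerator
#' `0.1 * (2 + z^-1 - z^-3 - 2 z^-4)` and a single real pole. The filter
#' state is initialised in steady state for the first frame's value, so
#' constant trajectories map exactly to zero.
#'
#' @param features Matrix frames x dims (or vector).
#' @param pole Real pole of the integrator (default 0.94).
#' @return Filtered features, same shape.
#' @export
rasta <- function(features, pole = 0.94) {
  vec <- is.null(dim(features))
  x <- if (vec) matrix(features, ncol = 1L) else features
  n <- nrow(x)
  if (n == 0L) return(features)
  b <- 0.1 * c(2, 1, 0, -1, -2)
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    # steady-state warm start: pretend the first value extends into the past
    pad <- c(rep(col[1L], 4L), col)
    fir <- as.double(stats::filter(pad, b, method = "convolution",
                                   sides = 1L))[-seq_len(4L)]
    out[, j] <- as.double(stats::filter(fir, pole, method = "recursive"))
  }
  if (vec) drop(out) else out
}
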