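#' Deconstruction configuration
#'
#' Parameters of the adaptive source-tract separation: the prediction
#' order of the inverse-filtering lattice, the exponential forgetting
#' factor shared by all recursions, the relative regularization constant
#' guarding every recursion denominator, and the burn-in interval
#' excluded from quality statistics.
#'
#' @param order_k Inverse-filter prediction order, integer in \[1, 64\].
#' @param forgetting Forgetting factor lambda in (0, 1\]; shipped presets
#'   use 0.995.
#' @param regularization Denominator guard, as a fraction of input power.
#' @param burn_in_s Burn-in excluded from quality statistics, seconds.
#'   Default (`NULL`): each lattice stage needs about one forgetting
#'   time-constant of settled input from the stage below, so the burn-in
#'   scales as `order_k` times the time-constant (at least 50 ms).
#' @param jpe_sweeps Ladder refinement sweeps: each sweep regresses the
#'   remaining estimation error on the backward prediction errors again,
#'   compensating their residual (non-ideal) correlation.
#' @return An object of class `decon_config`.
#' @export
decon_config <- function(order_k, forgetting = 0.995,
                         regularization = 1e-8, burn_in_s = NULL,
                         jpe_sweeps = 2) {
  order_k <- as.integer(order_k)
  if (is.na(order_k) || order_k < 1L || order_k > 64L)
    abort("`order_k` must be an integer in [1, 64].")
  if (forgetting <= 0 || forgetting > 1)
    abort("`forgetting` must lie in (0, 1].")
  if (regularization <= 0) abort("`regularization` must be positive.")
  if (is.null(burn_in_s)) {
    tau <- 1 / max((1 - forgetting) * 16000, 1)   # seconds at 16 kHz
    burn_in_s <- max(0.05, 1.25 * order_k * tau)
  }
  if (jpe_sweeps < 1) abort("`jpe_sweeps` must be >= 1.")
  structure(list(order_k = order_k, forgetting = forgetting,
                 regularization = regularization, burn_in_s = burn_in_s,
                 jpe_sweeps = as.integer(jpe_sweeps)),
            class = "decon_config")
}

#' @export
print.decon_config <- function(x, ...) {
  cat(sprintf("<decon_config> order %d, forgetting %.4f\n",
              x$order_k, x$forgetting))
  invisible(x)
}

#' Shipped per-corpus-style deconstruction presets
#'
#' Gender-dependent lattice orders tuned for a clean-microphone scenario
#' (`clean_*`) and a mobile-channel scenario (`mobile_*`), all with
#' forgetting factor 0.995.
#'
#' @return Tibble with columns `preset`, `gender`, `order_k`, `forgetting`.
#' @export
decon_presets <- function() {
  tibble(
    preset = c("clean_male", "clean_female", "mobile_male", "mobile_female"),
    gender = rep(c("male", "female"), 2L),
    order_k = c(10L, 16L, 24L, 36L),
    forgetting = 0.995
  )
}

#' Lip-radiation compensation
#'
#' A first-order adaptive prediction lattice tracks the exponentially
#' weighted lag-0/lag-1 autocorrelation of the input; the normalised
#' coefficient is read as the moment of a first-order radiation zero,
#' which is inverted by leaky integration, followed by DC removal.
#'
#' @param signal An `audio_signal` (or numeric vector).
#' @param forgetting Forgetting factor lambda.
#' @param regularization Denominator guard fraction.
#' @return An `audio_signal` with the compensated speech `s_l(n)`; the
#'   adapted coefficient trajectory is attached as attribute `"k"`.
#' @export
radiation_compensate <- function(signal, forgetting = 0.995,
                                 regularization = 1e-8) {
  x <- as_samples(signal)
  fs <- if (inherits(signal, "audio_signal")) signal$sample_rate else 16000
  res <- st_radiation_cpp(x, forgetting, regularization,
                          rho_max = 0.997, dc_pole = 0.995)
  out <- audio_signal(res$y, fs, meta = list(kind = "radiation_compensated"))
  attr(out, "k") <- res$k
  out
}

#' Adaptive lattice inverse filtering
#'
#' A k-order prediction-error lattice with exponentially weighted
#' error-product (Burg-type) coefficient recursions removes the vocal
#' tract information from the radiation-compensated speech; the residual
#' is the final-stage forward prediction error.
#'
#' @param s_l Radiation-compensated speech (`audio_signal` or numeric).
#' @param config A [decon_config()].
#' @return List with `residual` (`audio_signal`) and `parcor_traj`
#'   (order_k x n matrix of per-sample reflection coefficients).
#' @export
adaptive_lattice_residual <- function(s_l, config) {
  stopifnot(inherits(config, "decon_config"))
  x <- as_samples(s_l)
  fs <- if (inherits(s_l, "audio_signal")) s_l$sample_rate else 16000
  res <- st_lattice_cpp(x, config$order_k, config$forgetting,
                        config$regularization, keep_backward = FALSE)
  list(residual = audio_signal(res$residual, fs),
       parcor_traj = res$parcor)
}

#' Joint-process source-tract split
#'
#' The inverse-filter residual serves as the reference input of an
#' adaptive lattice-ladder joint-process estimator on the
#' radiation-compensated speech: the lattice orthogonalises the residual
#' into backward prediction errors, the ladder regresses `s_l(n)` on
#' them. The joint-process estimate (the component of `s_l` predictable
#' from the excitation-like residual) is the glottal source estimate; the
#' estimation error is the vocal tract estimate. The two components are
#' uncorrelated at second order and sum to `s_l` exactly.
#'
#' @inheritParams adaptive_lattice_residual
#' @return List with `gse` and `vte` (`audio_signal`s).
#' @export
joint_process_split <- function(s_l, config) {
  stopifnot(inherits(config, "decon_config"))
  x <- as_samples(s_l)
  fs <- if (inherits(s_l, "audio_signal")) s_l$sample_rate else 16000
  resid <- st_lattice_cpp(x, config$order_k, config$forgetting,
                          config$regularization, keep_backward = FALSE)$residual
  jpe <- st_jpe_cpp(resid, x, config$order_k, config$forgetting,
                    config$regularization, config$jpe_sweeps %||% 2L)
  list(gse = audio_signal(jpe$estimate, fs, meta = list(kind = "gse")),
       vte = audio_signal(jpe$error, fs, meta = list(kind = "vte")))
}

#' Deconstruct speech into glottal source and vocal tract estimates
#'
#' Chains the three stages: radiation compensation, k-order adaptive
#' lattice inverse filtering, and lattice-ladder joint-process
#' estimation.
#'
#' @param signal An `audio_signal`.
#' @param config A [decon_config()].
#' @return An object of class `decon_result` with fields `s_l`,
#'   `residual`, `gse`, `vte` (all `audio_signal`s of the input length),
#'   `parcor_traj` (order_k x n), and `config`.
#' @export
deconstruct <- function(signal, config) {
  stopifnot(inherits(signal, "audio_signal"), inherits(config, "decon_config"))
  s_l <- radiation_compensate(signal, config$forgetting,
                              config$regularization)
  lat <- adaptive_lattice_residual(s_l, config)
  jpe <- joint_process_split(s_l, config)
  structure(
    list(s_l = s_l, residual = lat$residual, gse = jpe$gse, vte = jpe$vte,
         parcor_traj = lat$parcor_traj, config = config),
    class = "decon_result"
  )
}

#' @export
print.decon_result <- function(x, ...) {
  cat(sprintf("<decon_result> %d samples, order %d, forgetting %.4f\n",
              length(x$s_l), x$config$order_k, x$config$forgetting))
  g <- glance(x)
  cat(sprintf("  |corr(gse, vte)| = %.4f; vte/s_l energy = %.3f\n",
              abs(g$gse_vte_cor), g$vte_energy_frac))
  invisible(x)
}

burn_in_index <- function(result) {
  n <- length(result$s_l)
  b <- min(n, floor(result$config$burn_in_s * result$s_l$sample_rate))
  if (n <= b) integer(0) else seq.int(b + 1L, n)
}

#' Tidy per-sample deconstruction trajectories
#'
#' @param x A `decon_result`.
#' @param ... Unused.
#' @return Tibble with one row per sample: `sample`, `s_l`, `residual`,
#'   `gse`, `vte`.
#' @export
tidy.decon_result <- function(x, ...) {
  tibble(sample = seq_along(x$s_l$samples), s_l = x$s_l$samples,
         residual = x$residual$samples, gse = x$gse$samples,
         vte = x$vte$samples)
}

#' One-row quality summary of a deconstruction
#'
#' Computed after burn-in: additivity error, source-tract correlation,
#' energy split, and the largest reflection-coefficient magnitude.
#'
#' @param x A `decon_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.decon_result <- function(x, ...) {
  idx <- burn_in_index(x)
  if (length(idx) < 2L)
    return(tibble(n = length(x$s_l), additivity_err = NA_real_,
                  gse_vte_cor = NA_real_, vte_energy_frac = NA_real_,
                  max_abs_parcor = NA_real_))
  sl <- x$s_l$samples; g <- x$gse$samples; v <- x$vte$samples
  add_err <- max(abs(g + v - sl)) / max(max(abs(sl)), 1e-300)
  cc <- if (sd(g[idx]) > 0 && sd(v[idx]) > 0) cor(g[idx], v[idx]) else 0
  tibble(n = length(x$s_l),
         additivity_err = add_err,
         gse_vte_cor = cc,
         vte_energy_frac = sum(v[idx]^2) / max(sum(sl[idx]^2), 1e-300),
         max_abs_parcor = if (length(x$parcor_traj)) max(abs(x$parcor_traj))
                          else NA_real_)
}

#' Spectral diagnostics: which branch carries which structure
#'
#' Checks the documented assignment criterion on one utterance: the VTE
#' envelope should carry resonance (formant) peaks, the GSE spectrum a
#' harmonic comb. Returns the measured formant peaks of both branches'
#' smoothed envelopes and the harmonicity (comb contrast at the given F0)
#' of both, so the assignment can be audited.
#'
#' @param result A `decon_result`.
#' @param f0 Fundamental frequency in Hz used for the comb measure.
#' @return One-row tibble with `gse_harmonicity`, `vte_harmonicity`, and
#'   a `vte_formants` list-column of envelope peak frequencies.
#' @export
decon_assignment_check <- function(result, f0) {
  fs <- result$s_l$sample_rate
  idx <- burn_in_index(result)
  g <- result$gse$samples[idx]; v <- result$vte$samples[idx]
  tibble(
    gse_harmonicity = comb_contrast(g, fs, f0),
    vte_harmonicity = comb_contrast(v, fs, f0),
    vte_formants = list(envelope_peaks(v, fs))
  )
}

#' Harmonic peak frequencies of the glottal source estimate
#'
#' High-resolution Welch spectrum of the GSE with parabolic peak
#' interpolation, searched near each multiple of the given F0.
#'
#' @param result A `decon_result`.
#' @param f0 Expected fundamental, Hz.
#' @param n_harmonics Number of harmonics to locate.
#' @return Numeric vector of measured peak frequencies (Hz).
#' @export
gse_harmonics <- function(result, f0, n_harmonics = 5) {
  idx <- burn_in_index(result)
  spectrum_harmonic_peaks(result$gse$samples[idx],
                          result$s_l$sample_rate, f0, n_harmonics)
}

#' Formant peak frequencies of the vocal tract estimate
#'
#' Welch power spectrum of the VTE smoothed into an envelope wide enough
#' to bridge the harmonic comb; local maxima are refined by parabolic
#' interpolation and returned ascending.
#'
#' @param result A `decon_result`.
#' @param n_formants Number of envelope peaks to return.
#' @param smooth_hz Envelope smoothing bandwidth (FWHM), Hz.
#' @return Numeric vector of envelope peak frequencies (Hz), ascending.
#' @export
vte_formants <- function(result, n_formants = 3, smooth_hz = 220) {
  idx <- burn_in_index(result)
  envelope_peaks(result$vte$samples[idx], result$s_l$sample_rate,
                 n_peaks = n_formants, smooth_hz = smooth_hz)
}
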