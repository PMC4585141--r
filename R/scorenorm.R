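#' Zero normalization (Z-norm) of trial scores
#'
#' Standardizes a raw score by the impostor-score distribution of the
#' target model: `S = (raw - mu_z) / sigma_z`.
#'
#' @param raw Raw LLR score(s).
#' @param stats Named list or vector with `mu` and `sigma` from
#'   [znorm_stats()].
#' @return Normalized score(s).
#' @export
znorm <- function(raw, stats) {
  mu <- stats[["mu"]]; sigma <- stats[["sigma"]]
  if (!is.finite(sigma) || sigma <= 0)
    abort("Normalization error: impostor score sigma must be positive.")
  (raw - mu) / sigma
}

#' Model-side impostor statistics for Z-norm
#'
#' Scores the target model against a cohort of impostor utterances and
#' returns the mean and standard deviation of those scores.
#'
#' @param model,ubm [gmm_diag()] models.
#' @param impostor_features List of feature sets (one per impostor
#'   utterance, >= 2).
#' @param aggregate Passed to [llr_score()].
#' @return List with `mu`, `sigma`, `n`.
#' @export
znorm_stats <- function(model, ubm, impostor_features,
                        aggregate = "mean") {
  if (length(impostor_features) < 2L)
    abort("Normalization error: need >= 2 impostor utterances.")
  s <- vapply(impostor_features,
              function(f) llr_score(model, ubm, f, aggregate), numeric(1))
  sigma <- sd(s)
  if (!is.finite(sigma) || sigma <= 0)
    abort("Normalization error: degenerate impostor score distribution.")
  list(mu = mean(s), sigma = sigma, n = length(s))
}

#' Test-side impostor statistics for T-norm
#'
#' Scores the test utterance against a cohort of impostor models; the
#' roles of model and test are swapped relative to Z-norm.
#'
#' @param features Test-utterance features.
#' @param impostor_models List of >= 2 [gmm_diag()] cohort models.
#' @param ubm The shared UBM.
#' @param aggregate Passed to [llr_score()].
#' @return List with `mu`, `sigma`, `n`.
#' @export
tnorm_stats <- function(features, impostor_models, ubm,
                        aggregate = "mean") {
  if (length(impostor_models) < 2L)
    abort("Normalization error: need >= 2 impostor models.")
  s <- vapply(impostor_models,
              function(m) llr_score(m, ubm, features, aggregate), numeric(1))
  sigma <- sd(s)
  if (!is.finite(sigma) || sigma <= 0)
    abort("Normalization error: degenerate impostor score distribution.")
  list(mu = mean(s), sigma = sigma, n = length(s))
}

#' @rdname znorm
#' @param stats_t T-norm statistics (from [tnorm_stats()]).
#' @export
tnorm <- function(raw, stats_t) znorm(raw, stats_t)

#' ZT-norm: Z-norm followed by T-norm
#'
#' The raw score is first Z-normalized with the target model's impostor
#' statistics; the result is then T-normalized with statistics computed
#' from equally Z-normalized impostor-model scores.
#'
#' @param raw Raw score.
#' @param stats_z Z-norm statistics for the target model.
#' @param stats_zt T-norm statistics computed on Z-normalized cohort
#'   scores.
#' @return Normalized score.
#' @export
ztnorm <- function(raw, stats_z, stats_zt) tnorm(znorm(raw, stats_z), stats_zt)
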