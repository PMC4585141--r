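#' False-acceptance / false-rejection error curve
#'
#' Exhaustive FAR/FRR counting over all candidate thresholds (the sorted
#' unique scores plus infinite sentinels). A trial is accepted iff its
#' score is greater than or equal to the threshold, so FAR is
#' non-increasing and FRR non-decreasing in the threshold; both are
#' percentages.
#'
#' @param target_scores Scores of target (same-speaker) trials.
#' @param nontarget_scores Scores of nontarget (impostor) trials.
#' @return A tibble of class `error_curve` with columns `threshold`,
#'   `far`, `frr` (percent).
#' @export
error_curve <- function(target_scores, nontarget_scores) {
  if (length(target_scores) < 1L || length(nontarget_scores) < 1L)
    abort("Both trial classes must be non-empty.")
  th <- c(-Inf, sort(unique(c(target_scores, nontarget_scores))), Inf)
  far <- vapply(th, function(t) 100 * mean(nontarget_scores >= t), numeric(1))
  frr <- vapply(th, function(t) 100 * mean(target_scores < t), numeric(1))
  out <- tibble(threshold = th, far = far, frr = frr)
  class(out) <- c("error_curve", class(out))
  attr(out, "n_target") <- length(target_scores)
  attr(out, "n_nontarget") <- length(nontarget_scores)
  out
}

#' Equal error rate and its operating threshold
#'
#' The threshold is the candidate minimizing `|FAR - FRR|` (ties broken
#' toward the lowest threshold); the EER is the mean of FAR and FRR
#' there.
#'
#' @param curve An [error_curve()].
#' @return List with `eer` (percent) and `threshold`.
#' @export
eer_and_threshold <- function(curve) {
  stopifnot(inherits(curve, "error_curve"))
  i <- which.min(abs(curve$far - curve$frr))
  list(eer = (curve$far[i] + curve$frr[i]) / 2, threshold = curve$threshold[i])
}

#' Half total error rate at a frozen threshold
#'
#' FAR and FRR are counted on the evaluation trials at the development
#' threshold; HTER is their mean.
#'
#' @param target_scores,nontarget_scores Evaluation-set trial scores.
#' @param threshold The development-set threshold.
#' @return HTER in percent.
#' @export
hter <- function(target_scores, nontarget_scores, threshold) {
  far <- 100 * mean(nontarget_scores >= threshold)
  frr <- 100 * mean(target_scores < threshold)
  (far + frr) / 2
}

#' Half equal error rate
#'
#' The mean of the male and female equal error rates; meaningful because
#' no cross-gender trials exist.
#'
#' @param eer_m,eer_f Per-gender EERs in percent.
#' @return HEER in percent.
#' @export
heer <- function(eer_m, eer_f) (eer_m + eer_f) / 2

#' Relative reduction of an error rate
#'
#' `RR = 100 * (baseline - new) / baseline`; negative values indicate
#' degradation.
#'
#' @param baseline,new Error rates in percent.
#' @return RR in percent.
#' @export
relative_reduction <- function(baseline, new) 100 * (baseline - new) / baseline

#' DET-curve coordinates
#'
#' FAR and FRR transformed by the inverse standard-normal distribution
#' function; rates are clamped away from 0 and 100 by half a trial
#' weight so all coordinates are finite.
#'
#' @param curve An [error_curve()].
#' @return Tibble with `threshold`, `det_far`, `det_frr` (probit units).
#' @export
det_points <- function(curve) {
  stopifnot(inherits(curve, "error_curve"))
  clamp <- function(r, n) pmin(pmax(r, 50 / n), 100 - 50 / n)
  tibble(threshold = curve$threshold,
         det_far = qnorm(clamp(curve$far, attr(curve, "n_nontarget")) / 100),
         det_frr = qnorm(clamp(curve$frr, attr(curve, "n_target")) / 100))
}

#' DET plot of one or more error curves
#'
#' @param object An [error_curve()].
#' @param ... Further named `error_curve`s to overlay.
#' @return A ggplot object (FRR against FAR on double-probit axes).
#' @export
autoplot.error_curve <- function(object, ...) {
  curves <- c(list(object), rlang::dots_list(...))
  names(curves)[1] <- names(curves)[1] %||% "system"
  if (is.null(names(curves))) names(curves) <- paste0("system", seq_along(curves))
  df <- purrr::imap_dfr(curves, function(cv, nm)
    dplyr::mutate(det_points(cv), system = nm))
  ticks <- c(0.1, 0.5, 1, 2, 5, 10, 20, 40)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$det_far, y = .data$det_frr,
                                   color = .data$system)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = qnorm(ticks / 100),
                                labels = ticks) +
    ggplot2::scale_y_continuous(breaks = qnorm(ticks / 100),
                                labels = ticks) +
    ggplot2::labs(x = "False acceptance rate (%)",
                  y = "False rejection rate (%)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Two-layer bootstrap standard error of a detection cost
#'
#' The statistic is a weighted sum of the miss and false-alarm
#' probabilities at a fixed threshold. Replicates resample speakers with
#' replacement (outer layer) and then each sampled speaker's trials
#' (inner layer), separately for the target and nontarget classes; the
#' standard error is the standard deviation of the replicate statistics.
#'
#' @param scores Tibble with columns `speaker`, `score`, `label`
#'   (`"target"` / `"nontarget"`).
#' @param threshold Fixed decision threshold.
#' @param c_miss,c_fa Cost weights of miss and false-alarm probabilities.
#' @param n_reps Number of bootstrap replications.
#' @param seed Integer seed.
#' @return List with `se`, `statistic` (the point estimate), and `n_reps`.
#' @export
bootstrap_se_dcf <- function(scores, threshold, c_miss = 1, c_fa = 1,
                             n_reps = 2000, seed = 1) {
  stopifnot(all(c("speaker", "score", "label") %in% names(scores)))
  tgt <- scores[scores$label == "target", ]
  non <- scores[scores$label == "nontarget", ]
  tgt_spk <- split(tgt$score, tgt$speaker)
  non_spk <- split(non$score, non$speaker)
  if (length(tgt_spk) < 2L || length(non_spk) < 2L)
    abort("Need >= 2 speakers per class for the two-layer bootstrap.")
  dcf <- function(ts, ns)
    c_miss * mean(ts < threshold) + c_fa * mean(ns >= threshold)
  resample_class <- function(spk_list) {
    ids <- sample.int(length(spk_list), replace = TRUE)
    unlist(lapply(spk_list[ids], function(s)
      s[sample.int(length(s), replace = TRUE)]), use.names = FALSE)
  }
  withr::with_seed(seed, {
    reps <- vapply(seq_len(n_reps), function(i)
      dcf(resample_class(tgt_spk), resample_class(non_spk)), numeric(1))
    list(se = sd(reps), statistic = dcf(tgt$score, non$score),
         n_reps = n_reps)
  })
}
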