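#' Extract features for every utterance of a corpus
#'
#' @param manifest Corpus manifest (see [generate_corpus()]).
#' @param configs Named list with `male` and `female` [gender_config()]s.
#' @param signals Optional named list of pre-loaded `audio_signal`s keyed
#'   by `utt_id` (otherwise WAVs are read from `manifest$path`).
#' @return Named list `utt_id -> feature_matrix` (each utterance
#'   processed with its own gender's configuration).
#' @export
extract_corpus_features <- function(manifest, configs, signals = NULL) {
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$utt_id
  for (i in seq_len(nrow(manifest))) {
    sig <- if (!is.null(signals)) signals[[manifest$utt_id[i]]]
           else read_wav(manifest$path[i])
    out[[i]] <- assemble_features(sig, configs[[manifest$gender[i]]])
  }
  out
}

check_split_hygiene <- function(manifest) {
  base_split <- sub("-(enroll|test)$", "", manifest$split)
  tab <- unique(tibble(speaker_id = manifest$speaker_id, split = base_split))
  dup <- tab$speaker_id[duplicated(tab$speaker_id)]
  if (length(dup))
    abort(paste("Split leakage: speaker(s) in multiple splits:",
                paste(unique(dup), collapse = ", ")))
  invisible(TRUE)
}

enroll_speakers <- function(manifest, split, features, ubm, relevance) {
  rows <- manifest[manifest$split == split, ]
  spk <- split(rows$utt_id, rows$speaker_id)
  lapply(spk, function(utts)
    map_adapt(ubm, features[utts], relevance,
              meta = list(n_utts = length(utts))))
}

score_trial_block <- function(models, manifest, split, features, ubm) {
  tests <- manifest[manifest$split == split, ]
  if (nrow(tests) == 0L) return(tibble())
  purrr::imap_dfr(models, function(model, model_id) {
    tibble(model_id = model_id,
           test_id = tests$utt_id,
           test_speaker = tests$speaker_id,
           raw = vapply(tests$utt_id, function(u)
             llr_score(model, ubm, features[[u]]), numeric(1)),
           label = ifelse(tests$speaker_id == model_id,
                          "target", "nontarget"))
  })
}

# Apply the configured score normalization to a trial block. Cohort
# material comes from the background split only.
apply_score_norm <- function(trials, kind, models, features, manifest, ubm,
                             relevance) {
  if (nrow(trials) == 0L || kind == "none") {
    trials$score <- trials$raw
    return(trials)
  }
  bg <- manifest[manifest$split == "background", ]
  bg_utts <- split(bg$utt_id, bg$speaker_id)
  z_stats_for <- function(exclude_speaker) {
    utts <- unlist(bg_utts[setdiff(names(bg_utts), exclude_speaker)],
                   use.names = FALSE)
    features[utts]
  }
  if (kind %in% c("znorm", "ztnorm")) {
    zs <- lapply(names(models), function(m)
      znorm_stats(models[[m]], ubm, z_stats_for(m)))
    names(zs) <- names(models)
  }
  if (kind %in% c("tnorm", "ztnorm")) {
    cohort <- enroll_speakers(manifest, "background", features, ubm,
                              relevance)
    if (length(cohort) < 2L)
      abort("Normalization error: need >= 2 background cohort speakers.")
    if (kind == "ztnorm") {
      cz <- lapply(names(cohort), function(m)
        znorm_stats(cohort[[m]], ubm, z_stats_for(m)))
      names(cz) <- names(cohort)
    }
  }
  score_one_test <- function(test_id) {
    rows <- which(trials$test_id == test_id)
    f <- features[[test_id]]
    if (kind == "znorm") {
      s <- vapply(rows, function(r)
        znorm(trials$raw[r], zs[[trials$model_id[r]]]), numeric(1))
    } else {
      cs <- vapply(names(cohort), function(m)
        llr_score(cohort[[m]], ubm, f), numeric(1))
      if (kind == "ztnorm")
        cs <- vapply(names(cohort), function(m)
          znorm(cs[m], cz[[m]]), numeric(1))
      st <- list(mu = mean(cs), sigma = sd(cs))
      if (!is.finite(st$sigma) || st$sigma <= 0)
        abort("Normalization error: degenerate cohort score distribution.")
      s <- vapply(rows, function(r) {
        r0 <- if (kind == "ztnorm")
          znorm(trials$raw[r], zs[[trials$model_id[r]]]) else trials$raw[r]
        tnorm(r0, st)
      }, numeric(1))
    }
    tibble(row = rows, score = s)
  }
  res <- purrr::map_dfr(unique(trials$test_id), score_one_test)
  trials$score <- NA_real_
  trials$score[res$row] <- res$score
  trials
}

run_gender <- function(manifest, config, features, seed) {
  ubm <- train_ubm(features[manifest$utt_id[manifest$split == "background"]],
                   G = config$n_gaussians, seed = seed,
                   meta = list(gender = config$gender))
  dev_models <- enroll_speakers(manifest, "dev-enroll", features, ubm,
                                config$map_relevance)
  dev_trials <- score_trial_block(dev_models, manifest, "dev-test",
                                  features, ubm)
  dev_trials <- apply_score_norm(dev_trials, config$score_norm, dev_models,
                                 features, manifest, ubm,
                                 config$map_relevance)
  curve <- error_curve(dev_trials$score[dev_trials$label == "target"],
                       dev_trials$score[dev_trials$label == "nontarget"])
  op <- eer_and_threshold(curve)

  hter_val <- NA_real_
  eval_trials <- tibble()
  if (any(manifest$split == "eval-enroll") &&
      any(manifest$split == "eval-test")) {
    eval_models <- enroll_speakers(manifest, "eval-enroll", features, ubm,
                                   config$map_relevance)
    eval_trials <- score_trial_block(eval_models, manifest, "eval-test",
                                     features, ubm)
    eval_trials <- apply_score_norm(eval_trials, config$score_norm,
                                    eval_models, features, manifest, ubm,
                                    config$map_relevance)
    hter_val <- hter(eval_trials$score[eval_trials$label == "target"],
                     eval_trials$score[eval_trials$label == "nontarget"],
                     op$threshold)
  }
  list(eer = op$eer, threshold = op$threshold, hter = hter_val,
       curve = curve, dev_trials = dev_trials, eval_trials = eval_trials,
       ubm = ubm, config = config)
}

#' Run the full per-gender verification protocol
#'
#' Per gender: train the background model, MAP-enroll the development
#' (and, if present, evaluation) targets, score all same-gender
#' model-test trials, apply the configured score normalization, find the
#' development EER and threshold, and compute the evaluation HTER at the
#' frozen development threshold. Male and female pipelines share no
#' fitted state.
#'
#' @param manifest Corpus manifest covering at least the background and
#'   dev splits for each gender present in `configs`.
#' @param configs Named list of [gender_config()]s (`male`, `female`, or
#'   both).
#' @param seed Integer seed (UBM training).
#' @param features Optional precomputed feature list (from
#'   [extract_corpus_features()]).
#' @return Object of class `eval_report`.
#' @export
run_experiment <- function(manifest, configs, seed = 1, features = NULL) {
  check_split_hygiene(manifest)
  genders <- names(configs)
  stopifnot(all(genders %in% c("male", "female")))
  if (is.null(features))
    features <- extract_corpus_features(
      manifest[manifest$gender %in% genders, ], configs)
  res <- lapply(genders, function(g)
    run_gender(manifest[manifest$gender == g, ], configs[[g]], features,
               seed))
  names(res) <- genders
  heer_val <- if (all(c("male", "female") %in% genders))
    heer(res$male$eer, res$female$eer) else NA_real_
  structure(list(genders = res, heer = heer_val, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(tidy(x))
  if (is.finite(x$heer)) cat(sprintf("HEER = %.3f%%\n", x$heer))
  invisible(x)
}

#' Per-gender rates of an experiment report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble: `gender`, `eer`, `threshold`, `hter`, trial counts.
#' @export
tidy.eval_report <- function(x, ...) {
  purrr::imap_dfr(x$genders, function(r, g)
    tibble(gender = g, eer = r$eer, threshold = r$threshold, hter = r$hter,
           n_dev_trials = nrow(r$dev_trials),
           n_eval_trials = nrow(r$eval_trials),
           score_norm = r$config$score_norm))
}

#' @describeIn tidy.eval_report One-row summary with HEER.
#' @export
glance.eval_report <- function(x, ...) {
  td <- tidy(x)
  tibble(heer = x$heer,
         eer_m = td$eer[match("male", td$gender)],
         eer_f = td$eer[match("female", td$gender)],
         hter_m = td$hter[match("male", td$gender)],
         hter_f = td$hter[match("female", td$gender)],
         seed = x$seed)
}

#' Relative reductions of one report against a named baseline
#'
#' @param report,baseline `eval_report`s on the same protocol.
#' @return Tibble with per-gender EER/HTER relative reductions and the
#'   HEER relative reduction (percent).
#' @export
compare_reports <- function(report, baseline) {
  a <- tidy(report); b <- tidy(baseline)
  j <- dplyr::inner_join(a, b, by = "gender", suffix = c("", "_base"))
  out <- dplyr::transmute(
    j, gender = .data$gender,
    eer = .data$eer, eer_baseline = .data$eer_base,
    eer_rr = relative_reduction(.data$eer_base, .data$eer),
    hter_rr = relative_reduction(.data$hter_base, .data$hter))
  attr(out, "heer_rr") <- relative_reduction(baseline$heer, report$heer)
  out
}

#' Grid search of front-end and back-end meta-parameters
#'
#' Exhaustive ("deep") search over the Cartesian grid, evaluated by
#' development-set EER per gender only; the evaluation split is never
#' touched. Ties rank toward the smaller model (fewer Gaussians, then
#' lower lattice order).
#'
#' @param manifest Corpus manifest.
#' @param config Base [gender_config()] for one gender.
#' @param grid Named list of candidate vectors among `order_k`,
#'   `forgetting`, `n_filters`, `n_mfcc`, `n_gaussians`,
#'   `map_relevance`.
#' @param seed Integer seed.
#' @return Tibble of configurations ranked by dev EER (rank 1 = best).
#' @export
grid_search <- function(manifest, config, grid, seed = 1) {
  if (!length(grid)) abort("`grid` must be non-empty.")
  allowed <- c("order_k", "forgetting", "n_filters", "n_mfcc",
               "n_gaussians", "map_relevance")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) abort(paste("Unknown grid axes:", paste(bad, collapse = ", ")))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  g <- config$gender
  man_g <- manifest[manifest$gender == g &
                      manifest$split %in% c("background", "dev-enroll",
                                            "dev-test"), ]
  results <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    cfg <- config
    row <- combos[i, , drop = FALSE]
    if (!is.null(row$order_k) && !is.null(cfg$decon))
      cfg$decon$order_k <- as.integer(row$order_k)
    if (!is.null(row$forgetting) && !is.null(cfg$decon))
      cfg$decon$forgetting <- row$forgetting
    if (!is.null(row$n_filters)) cfg$speech_stream$n_filters <- row$n_filters
    if (!is.null(row$n_mfcc)) cfg$speech_stream$n_mfcc <- row$n_mfcc
    if (!is.null(row$n_gaussians)) cfg$n_gaussians <- row$n_gaussians
    if (!is.null(row$map_relevance)) cfg$map_relevance <- row$map_relevance
    configs <- list(cfg); names(configs) <- g
    rep <- run_experiment(man_g, configs, seed = seed)
    dplyr::bind_cols(as_tibble(row),
                     tibble(eer = rep$genders[[g]]$eer,
                            n_gaussians_eff = cfg$n_gaussians,
                            order_k_eff = cfg$decon$order_k %||% NA_integer_))
  })
  results <- dplyr::arrange(results, .data$eer, .data$n_gaussians_eff,
                            .data$order_k_eff)
  results$rank <- seq_len(nrow(results))
  results
}
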