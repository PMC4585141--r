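#' Speaker specification for synthetic voice generation
#'
#' Describes one synthetic speaker under the classical source-filter
#' production model: a glottal pulse train (two-phase flow-derivative
#' pulse: opening polynomial plus exponential return) excites an all-pole
#' vocal tract, followed by lip radiation (first difference).
#'
#' @param speaker_id Opaque label.
#' @param gender `"male"` or `"female"`.
#' @param f0_mean Mean fundamental frequency, Hz (> 0).
#' @param f0_sd Slow intonation wander, Hz.
#' @param jitter Fractional cycle-length perturbation, in \[0, 0.2\].
#' @param shimmer Fractional pulse-amplitude perturbation, in \[0, 0.2\].
#' @param lf_shape Named numeric: `oq` open quotient in \[0.3, 0.9\] and
#'   `rq` return-phase quotient (fraction of the cycle) in \[0.01, 0.25\].
#' @param formants Two-column matrix or list of `(center_hz, bandwidth_hz)`
#'   pairs, centers strictly ascending.
#' @param tract_length_scale Vocal-tract length multiplier; formant
#'   centers scale as `1 / tract_length_scale` (longer tract, lower
#'   formants).
#' @return An object of class `speaker_spec`.
#' @export
speaker_spec <- function(speaker_id, gender, f0_mean, f0_sd = 2,
                         jitter = 0.01, shimmer = 0.03,
                         lf_shape = c(oq = 0.6, rq = 0.05),
                         formants = default_formants(gender),
                         tract_length_scale = 1) {
  gender <- match.arg(gender, c("male", "female"))
  formants <- as_formant_matrix(formants)
  if (f0_mean <= 0) abort("`f0_mean` must be positive.")
  if (jitter < 0 || jitter > 0.2 || shimmer < 0 || shimmer > 0.2)
    abort("`jitter` and `shimmer` must lie in [0, 0.2].")
  check_lf_shape(lf_shape)
  if (nrow(formants) > 0) {
    if (any(diff(formants[, 1L]) <= 0))
      abort("Formant centers must be strictly increasing.")
    if (any(formants[, 2L] <= 0)) abort("Formant bandwidths must be positive.")
  }
  if (tract_length_scale <= 0) abort("`tract_length_scale` must be positive.")
  structure(
    list(speaker_id = as.character(speaker_id), gender = gender,
         f0_mean = f0_mean, f0_sd = f0_sd, jitter = jitter, shimmer = shimmer,
         lf_shape = lf_shape, formants = formants,
         tract_length_scale = tract_length_scale),
    class = "speaker_spec"
  )
}

check_lf_shape <- function(lf_shape) {
  if (!all(c("oq", "rq") %in% names(lf_shape)))
    abort("`lf_shape` must contain `oq` and `rq`.")
  oq <- lf_shape[["oq"]]; rq <- lf_shape[["rq"]]
  if (!is.finite(oq) || oq < 0.3 || oq > 0.9)
    abort("`lf_shape[\"oq\"]` must lie in [0.3, 0.9].")
  if (!is.finite(rq) || rq < 0.01 || rq > 0.25)
    abort("`lf_shape[\"rq\"]` must lie in [0.01, 0.25].")
  invisible(lf_shape)
}

as_formant_matrix <- function(formants) {
  if (is.null(formants)) return(matrix(numeric(0), 0L, 2L))
  if (is.list(formants) && !is.data.frame(formants))
    formants <- do.call(rbind, formants)
  formants <- as.matrix(formants)
  if (length(formants) == 0L) return(matrix(numeric(0), 0L, 2L))
  if (ncol(formants) != 2L)
    abort("`formants` must be (center_hz, bandwidth_hz) pairs.")
  unname(formants)
}

#' Gender-template formant sets
#'
#' Neutral-vowel templates used as the hyper-distribution centers for
#' synthetic speaker populations.
#'
#' @param gender `"male"` or `"female"`.
#' @return Matrix of (center Hz, bandwidth Hz) rows.
#' @export
default_formants <- function(gender = c("male", "female")) {
  gender <- match.arg(gender)
  m <- cbind(c(500, 1500, 2500, 3500), c(60, 90, 120, 160))
  if (gender == "female") m[, 1L] <- m[, 1L] * 1.15
  m
}

#' @export
print.speaker_spec <- function(x, ...) {
  cat(sprintf("<speaker_spec> %s (%s): F0 %.1f Hz, %d formants\n",
              x$speaker_id, x$gender, x$f0_mean, nrow(x$formants)))
  invisible(x)
}

#' Glottal flow-derivative pulse train
#'
#' Generates the voice-source excitation: one two-phase pulse per
#' fundamental period (a polynomial opening/closing phase with its
#' characteristic negative closure spike, smoothed by an exponential
#' return phase), with multiplicative jitter on cycle lengths and shimmer
#' on pulse amplitudes.
#'
#' @param f0_contour F0 in Hz, either a scalar or one value per output
#'   sample; must lie in (20, `sample_rate`/4).
#' @param lf_shape Named numeric with `oq` and `rq`, see [speaker_spec()].
#' @param jitter,shimmer Fractional perturbations (>= 0).
#' @param duration Duration in seconds (>= 0).
#' @param sample_rate Sample rate, Hz.
#' @param seed Integer seed; output is a pure function of arguments.
#' @return An `audio_signal` holding the glottal flow derivative.
#' @export
lf_pulse_train <- function(f0_contour, lf_shape = c(oq = 0.6, rq = 0.05),
                           jitter = 0, shimmer = 0, duration = 1,
                           sample_rate = 16000, seed = 1) {
  check_lf_shape(lf_shape)
  if (duration < 0) abort("`duration` must be >= 0.")
  n <- floor(duration * sample_rate)
  if (n == 0L) return(audio_signal(numeric(0), sample_rate))
  f0 <- rep_len(as.double(f0_contour), n)
  if (any(f0 <= 20 | f0 >= sample_rate / 4))
    abort("`f0_contour` must lie in (20, sample_rate / 4).")
  oq <- lf_shape[["oq"]]; rq <- lf_shape[["rq"]]
  withr::with_seed(seed, {
    out <- numeric(n)
    pos <- 1L
    while (pos <= n) {
      t_samp <- sample_rate / f0[pos]
      if (jitter > 0)
        t_samp <- t_samp * (1 + jitter * max(-3, min(3, rnorm(1))))
      period <- max(4L, as.integer(round(t_samp)))
      amp <- 1
      if (shimmer > 0)
        amp <- max(0.05, 1 + shimmer * max(-3, min(3, rnorm(1))))
      n_open <- max(2L, as.integer(round(oq * period)))
      s <- seq_len(n_open) / n_open
      pulse <- amp * (2 * s - 3 * s^2)   # flow derivative, closure spike -amp
      last <- min(n, pos + n_open - 1L)
      out[pos:last] <- pulse[seq_len(last - pos + 1L)]
      pos <- pos + period
    }
    # exponential return phase: one-pole smoothing with time constant
    # rq * mean period, applied across the whole train
    rho <- exp(-1 / (rq * sample_rate / mean(f0)))
    out <- as.double(stats::filter(out * (1 - rho), rho, method = "recursive"))
    audio_signal(out, sample_rate,
                 meta = list(kind = "glottal_flow_derivative"))
  })
}

#' All-pole vocal tract filter from formant specifications
#'
#' One conjugate pole pair per formant: pole radius `exp(-pi * bw / fs)`,
#' angle `2 * pi * f / fs`. Returns the denominator polynomial of the
#' all-pole transfer function (leading coefficient 1); an empty formant
#' list yields the identity filter.
#'
#' @param formants (center Hz, bandwidth Hz) pairs, centers < `fs`/2.
#' @param sample_rate Sample rate, Hz.
#' @return Numeric vector of denominator coefficients `a`, `a[1] == 1`.
#' @export
make_tract_filter <- function(formants, sample_rate) {
  formants <- as_formant_matrix(formants)
  if (nrow(formants) == 0L) return(1)
  if (any(formants[, 1L] >= sample_rate / 2))
    abort("Formant centers must be below the Nyquist frequency.")
  if (any(formants[, 2L] <= 0)) abort("Bandwidths must be positive.")
  a <- 1
  for (i in seq_len(nrow(formants))) {
    r <- exp(-pi * formants[i, 2L] / sample_rate)
    th <- 2 * pi * formants[i, 1L] / sample_rate
    a <- convolve(a, rev(c(1, -2 * r * cos(th), r^2)), type = "open")
  }
  a
}

#' Synthesize one utterance from a speaker specification
#'
#' Composition of the production model: glottal pulse train, all-pole
#' tract filtering, first-difference lip radiation, peak normalisation,
#' short leading/trailing silence, and optional additive white noise at a
#' given SNR (measured over the voiced region).
#'
#' @param spec A [speaker_spec()].
#' @param duration Voiced duration, seconds.
#' @param snr_db Signal-to-noise ratio in dB, or `NULL` for noiseless.
#' @param seed Integer seed.
#' @param sample_rate Sample rate, Hz.
#' @param silence_s Leading/trailing silence, seconds.
#' @return An `audio_signal`.
#' @export
synthesize_utterance <- function(spec, duration, snr_db = NULL, seed = 1,
                                 sample_rate = 16000, silence_s = 0.15) {
  stopifnot(inherits(spec, "speaker_spec"))
  n <- floor(duration * sample_rate)
  withr::with_seed(seed, {
    # slow intonation wander: heavily smoothed white noise, sd f0_sd
    f0 <- spec$f0_mean
    if (n > 0L && spec$f0_sd > 0) {
      w <- as.double(stats::filter(rnorm(n), 0.999, method = "recursive"))
      w <- w / max(sd(w), 1e-12) * spec$f0_sd
      f0 <- pmax(30, spec$f0_mean + w)
    }
    exc <- lf_pulse_train(f0, spec$lf_shape, spec$jitter, spec$shimmer,
                          duration, sample_rate,
                          seed = sample.int(.Machine$integer.max, 1L))
    fm <- spec$formants
    if (nrow(fm) > 0L) {
      fm[, 1L] <- pmin(fm[, 1L] / spec$tract_length_scale,
                       0.45 * sample_rate)
      a <- make_tract_filter(fm, sample_rate)
      voiced <- as.double(stats::filter(exc$samples, -a[-1L],
                                        method = "recursive"))
    } else {
      voiced <- exc$samples
    }
    # syllabic-rate amplitude modulation: real utterances carry 2-5 Hz
    # energy rhythm, which keeps frame energy informative downstream
    if (length(voiced) > 0L) {
      rate <- runif(1, 2.5, 5); depth <- runif(1, 0.25, 0.5)
      ph <- runif(1, 0, 2 * pi)
      tt <- seq_along(voiced) / sample_rate
      voiced <- voiced * ((1 - depth) +
                            depth * (0.5 + 0.5 * sin(2 * pi * rate * tt + ph)))
    }
    voiced <- diff(c(0, voiced))                     # lip radiation
    if (length(voiced) > 0L)
      voiced <- voiced / max(abs(voiced), 1e-12) * 0.7
    pad <- numeric(floor(silence_s * sample_rate))
    s <- c(pad, voiced, pad)
    if (!is.null(snr_db) && !is.na(snr_db) && length(s) > 0L) {
      p_sig <- mean(voiced^2)
      p_noise <- p_sig / 10^(snr_db / 10)
      s <- s + rnorm(length(s), sd = sqrt(p_noise))
    }
    audio_signal(s, sample_rate,
                 meta = list(speaker_id = spec$speaker_id,
                             gender = spec$gender, seed = seed,
                             f0_mean = spec$f0_mean,
                             voiced_range = c(length(pad) + 1L,
                                              length(pad) + length(voiced))))
  })
}

#' Draw a population of synthetic speakers
#'
#' Per-gender hyper-distributions: male `f0_mean ~ N(120, 10)` truncated
#' to \[90, 155\] Hz and female `f0_mean ~ N(210, 12)` truncated to
#' \[175, 255\] Hz (the two gender pitch priors, with disjoint supports);
#' per-speaker formant centers are the gender template perturbed by
#' independent Gaussian factors (sd 5%) and a tract-length scale
#' `~ N(1, 0.04)`; jitter, shimmer and glottal shape parameters are drawn
#' uniformly over physiologically plausible ranges.
#'
#' @param n Number of speakers.
#' @param gender `"male"` or `"female"`.
#' @param seed Integer seed.
#' @param id_prefix Prefix for speaker ids.
#' @return List of [speaker_spec()] objects.
#' @export
sample_speakers <- function(n, gender = c("male", "female"), seed = 1,
                            id_prefix = NULL) {
  gender <- match.arg(gender)
  id_prefix <- id_prefix %||% toupper(substr(gender, 1L, 1L))
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      f0 <- if (gender == "male") {
        min(155, max(90, rnorm(1, 120, 10)))
      } else {
        min(255, max(175, rnorm(1, 210, 12)))
      }
      fm <- default_formants(gender)
      centers <- fm[, 1L] * (1 + rnorm(nrow(fm), 0, 0.05))
      fm[, 1L] <- sort(pmin(centers, 7000))
      fm[, 2L] <- fm[, 2L] * runif(nrow(fm), 0.9, 1.1)
      speaker_spec(
        speaker_id = sprintf("%s%03d", id_prefix, i), gender = gender,
        f0_mean = f0, f0_sd = runif(1, 1, 4),
        jitter = runif(1, 0.005, 0.02), shimmer = runif(1, 0.02, 0.06),
        lf_shape = c(oq = runif(1, 0.5, 0.75), rq = runif(1, 0.03, 0.12)),
        formants = fm,
        tract_length_scale = min(1.15, max(0.85, rnorm(1, 1, 0.04)))
      )
    })
  })
}

#' Generate a synthetic speaker-verification corpus
#'
#' Draws per-gender speaker populations, assigns speakers to background /
#' development / evaluation splits, synthesizes all utterances to WAV
#' files, and returns the corpus manifest. Within development and
#' evaluation splits, the first `enroll_per_speaker` utterances of each
#' speaker are enrollment material and the rest are test material.
#'
#' @param out_dir Directory for WAV files (created if missing).
#' @param n_speakers_per_gender Speakers per gender (>= 1).
#' @param utterances_per_speaker Utterances per speaker (>= 1).
#' @param duration_mean,duration_sd Utterance duration statistics in
#'   seconds (Gaussian, clamped to \[1.5, 10\]).
#' @param snr_db Additive-noise SNR in dB, or `NULL` for clean speech.
#' @param split_counts Named integer vector `c(background=, dev=, eval=)`
#'   of speakers per split per gender; `eval` may be 0. Defaults to an
#'   even background/dev/eval split.
#' @param enroll_per_speaker Enrollment utterances per dev/eval speaker;
#'   default: 3, capped at one less than `utterances_per_speaker`.
#' @param sample_rate Sample rate, Hz.
#' @param seed Integer seed; manifest and audio are pure functions of it.
#' @return A tibble manifest: `speaker_id`, `gender`, `split`, `utt_id`,
#'   `path`, `duration`, `seed`.
#' @export
generate_corpus <- function(out_dir,
                            n_speakers_per_gender = 8,
                            utterances_per_speaker = 10,
                            duration_mean = 4, duration_sd = 0.5,
                            snr_db = NULL,
                            split_counts = NULL,
                            enroll_per_speaker = NULL,
                            sample_rate = 16000,
                            seed = 1) {
  if (n_speakers_per_gender < 1 || utterances_per_speaker < 1)
    abort("Speaker and utterance counts must be >= 1.")
  if (is.null(split_counts)) {
    n_bg <- max(1L, floor(n_speakers_per_gender / 2))
    # at least two development speakers whenever possible, so both
    # target and nontarget trials exist
    n_dev <- max(min(2L, n_speakers_per_gender - n_bg),
                 ceiling((n_speakers_per_gender - n_bg) / 2))
    n_ev <- n_speakers_per_gender - n_bg - n_dev
    split_counts <- c(background = n_bg, dev = n_dev, eval = n_ev)
  }
  if (sum(split_counts) != n_speakers_per_gender)
    abort("`split_counts` must sum to `n_speakers_per_gender`.")
  if (split_counts[["dev"]] < 1)
    abort("Configuration error: at least one development speaker is required.")
  enroll_per_speaker <- enroll_per_speaker %||%
    min(3L, max(1L, utterances_per_speaker - 1L))
  if (enroll_per_speaker < 1 || enroll_per_speaker >= utterances_per_speaker)
    abort(paste("Configuration error: the split plan must leave every",
                "dev/eval speaker with >= 1 enrollment and >= 1 test",
                "utterance."))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- withr::with_seed(seed, {
    res <- list()
    for (g in c("male", "female")) {
      specs <- sample_speakers(n_speakers_per_gender, g,
                               seed = sample.int(.Machine$integer.max, 1L))
      split_of <- rep(c("background", "dev", "eval"),
                      times = c(split_counts[["background"]],
                                split_counts[["dev"]],
                                split_counts[["eval"]]))
      for (i in seq_along(specs)) {
        spec <- specs[[i]]
        for (u in seq_len(utterances_per_speaker)) {
          dur <- min(10, max(1.5, rnorm(1, duration_mean, duration_sd)))
          useed <- sample.int(.Machine$integer.max - 1L, 1L)
          split <- split_of[i]
          if (split != "background")
            split <- paste0(split,
                            if (u <= enroll_per_speaker) "-enroll" else "-test")
          utt_id <- sprintf("%s_u%02d", spec$speaker_id, u)
          res[[length(res) + 1L]] <- list(
            spec = spec, utt_id = utt_id, split = split, duration = dur,
            useed = useed)
        }
      }
    }
    res
  })
  manifest <- purrr::map_dfr(rows, function(r) {
    sig <- synthesize_utterance(r$spec, r$duration, snr_db = snr_db,
                                seed = r$useed, sample_rate = sample_rate)
    path <- file.path(out_dir, paste0(r$utt_id, ".wav"))
    write_wav(sig, path)
    tibble(speaker_id = r$spec$speaker_id, gender = r$spec$gender,
           split = r$split, utt_id = r$utt_id, path = path,
           duration = r$duration, seed = r$useed)
  })
  attr(manifest, "speaker_seed") <- seed
  manifest
}

#' Write / read a corpus manifest as delimited text
#'
#' @param manifest Manifest tibble from [generate_corpus()].
#' @param path File path.
#' @return The manifest (read) or `path` invisibly (write).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}
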