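# Shared fixtures, built in code. The cache keeps expensive objects
# (synthetic vowels, small corpora) alive across test files in one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# Canonical sustained vowel: 120 Hz, three formants at 500/1500/2500 Hz.
canonical_vowel_spec <- function(jitter = 0, shimmer = 0, f0_sd = 0) {
  speaker_spec("vowel", "male", 120, f0_sd = f0_sd, jitter = jitter,
               shimmer = shimmer,
               formants = cbind(c(500, 1500, 2500), c(60, 90, 120)))
}

canonical_vowel <- function(duration = 2, seed = 7) {
  cached(sprintf("vowel_%g_%d", duration, seed),
         synthesize_utterance(canonical_vowel_spec(), duration, seed = seed))
}

# Small clean corpus shared across experiment tests.
small_corpus <- function() {
  cached("small_corpus", {
    dir <- file.path(tempdir(), "stract_small_corpus")
    generate_corpus(dir, n_speakers_per_gender = 4,
                    utterances_per_speaker = 4, duration_mean = 2,
                    duration_sd = 0.2,
                    split_counts = c(background = 2, dev = 2, eval = 0),
                    enroll_per_speaker = 2, seed = 404)
  })
}

small_config <- function(gender, gse = FALSE) {
  gender_config(
    gender,
    speech_stream = list(n_filters = 24, n_mfcc = 12, use_delta = TRUE,
                         use_double_delta = FALSE),
    gse_stream = if (gse) list(n_filters = 13, n_mfcc = 6),
    decon = if (gse) decon_config(if (gender == "male") 10 else 16, 0.995),
    n_gaussians = 8, map_relevance = 16)
}
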