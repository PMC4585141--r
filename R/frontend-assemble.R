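#' Per-gender front-end and back-end configuration
#'
#' Describes one gender's feature vector layout (speech / glottal-source
#' / vocal-tract MFCC streams plus extras), the deconstruction settings
#' feeding the GSE/VTE streams, and the back-end model size.
#'
#' @param gender `"male"` or `"female"`.
#' @param speech_stream List: `n_filters`, `n_mfcc`, `use_delta`,
#'   `use_double_delta`.
#' @param gse_stream,vte_stream List `(n_filters, n_mfcc)` or `NULL` to
#'   disable the stream.
#' @param extras Character subset of `c("E", "dE", "F0", "F3")`.
#' @param decon A [decon_config()] (required when a GSE or VTE stream is
#'   requested).
#' @param n_gaussians Mixture size G of the gender-dependent models.
#' @param map_relevance MAP relevance factor alpha.
#' @param score_norm One of `"none"`, `"znorm"`, `"tnorm"`, `"ztnorm"`.
#' @param fp [frame_params()].
#' @param f0_range F0 search range, Hz (gender dependent).
#' @param warp_window Feature-warping window in frames.
#' @param use_denoise Apply spectral-amplitude denoising first.
#' @param unvoiced_fill `"hold"` (carry the last voiced value within a
#'   segment) or `"zero"` for unvoiced F0/F3 frames.
#' @return An object of class `gender_config`.
#' @export
gender_config <- function(gender = c("male", "female"),
                          speech_stream = list(n_filters = 34, n_mfcc = 26,
                                               use_delta = TRUE,
                                               use_double_delta = FALSE),
                          gse_stream = NULL, vte_stream = NULL,
                          extras = character(0),
                          decon = NULL,
                          n_gaussians = 32, map_relevance = 16,
                          score_norm = c("none", "znorm", "tnorm", "ztnorm"),
                          fp = frame_params(),
                          f0_range = NULL,
                          warp_window = 301,
                          use_denoise = TRUE,
                          unvoiced_fill = c("hold", "zero")) {
  gender <- match.arg(gender)
  score_norm <- match.arg(score_norm)
  unvoiced_fill <- match.arg(unvoiced_fill)
  extras <- unique(as.character(extras))
  bad <- setdiff(extras, c("E", "dE", "F0", "F3"))
  if (length(bad)) abort(paste("Unknown extras:", paste(bad, collapse = ", ")))
  for (s in list(speech_stream, gse_stream, vte_stream)) {
    if (!is.null(s) && s$n_mfcc >= s$n_filters)
      abort("`n_mfcc` must be < `n_filters` for every stream.")
  }
  if ((!is.null(gse_stream) || !is.null(vte_stream)) && is.null(decon))
    abort("Configuration error: GSE/VTE streams require a `decon` config.")
  f0_range <- f0_range %||%
    if (gender == "male") c(60, 250) else c(120, 400)
  structure(
    list(gender = gender, speech_stream = speech_stream,
         gse_stream = gse_stream, vte_stream = vte_stream,
         extras = extras, decon = decon, n_gaussians = n_gaussians,
         map_relevance = map_relevance, score_norm = score_norm,
         fp = fp, f0_range = f0_range, warp_window = warp_window,
         use_denoise = use_denoise, unvoiced_fill = unvoiced_fill),
    class = "gender_config"
  )
}

#' @export
print.gender_config <- function(x, ...) {
  streams <- c(
    sprintf("speech %d/%d%s", x$speech_stream$n_filters,
            x$speech_stream$n_mfcc,
            if (isTRUE(x$speech_stream$use_delta)) "+d" else ""),
    if (!is.null(x$gse_stream))
      sprintf("gse %d/%d", x$gse_stream$n_filters, x$gse_stream$n_mfcc),
    if (!is.null(x$vte_stream))
      sprintf("vte %d/%d", x$vte_stream$n_filters, x$vte_stream$n_mfcc))
  cat(sprintf("<gender_config> %s: %s; extras: %s; G=%d alpha=%g; norm=%s\n",
              x$gender, paste(streams, collapse = ", "),
              if (length(x$extras)) paste(x$extras, collapse = "+") else "-",
              x$n_gaussians, x$map_relevance, x$score_norm))
  invisible(x)
}

#' Shipped per-gender configuration presets
#'
#' The tuned configurations for the two scenarios: a clean-microphone
#' scenario (`clean_*`) and a mobile-channel scenario (`mobile_*`),
#' each as gender-dependent extended-biometric setups, plus the
#' gender-independent MFCC+delta baselines (`*_gic`). Back-end sizes are
#' the full-scale values; desk-scale runs override `n_gaussians`.
#'
#' @param name Preset name, see Details.
#' @return A [gender_config()].
#' @details Available presets: `clean_gic`, `clean_male`, `clean_female`,
#'   `mobile_gic`, `mobile_male`, `mobile_female`.
#' @export
gender_preset <- function(name) {
  switch(
    name,
    clean_gic = gender_config(
      "male",
      speech_stream = list(n_filters = 34, n_mfcc = 26, use_delta = TRUE,
                           use_double_delta = FALSE),
      n_gaussians = 256, map_relevance = 5),
    clean_male = gender_config(
      "male",
      speech_stream = list(n_filters = 34, n_mfcc = 26, use_delta = TRUE,
                           use_double_delta = FALSE),
      gse_stream = list(n_filters = 13, n_mfcc = 8),
      extras = c("E", "dE"),
      decon = decon_config(10, 0.995),
      n_gaussians = 256, map_relevance = 16),
    clean_female = gender_config(
      "female",
      speech_stream = list(n_filters = 44, n_mfcc = 26, use_delta = TRUE,
                           use_double_delta = FALSE),
      gse_stream = list(n_filters = 12, n_mfcc = 4),
      extras = c("E", "dE", "F0", "F3"),
      decon = decon_config(16, 0.995),
      n_gaussians = 256, map_relevance = 5),
    mobile_gic = gender_config(
      "male",
      speech_stream = list(n_filters = 30, n_mfcc = 27, use_delta = TRUE,
                           use_double_delta = FALSE),
      n_gaussians = 256, map_relevance = 24),
    mobile_male = gender_config(
      "male",
      speech_stream = list(n_filters = 44, n_mfcc = 25, use_delta = TRUE,
                           use_double_delta = FALSE),
      gse_stream = list(n_filters = 7, n_mfcc = 6),
      extras = c("dE", "F0", "F3"),
      decon = decon_config(24, 0.995),
      n_gaussians = 1024, map_relevance = 24),
    mobile_female = gender_config(
      "female",
      speech_stream = list(n_filters = 34, n_mfcc = 24, use_delta = TRUE,
                           use_double_delta = FALSE),
      gse_stream = list(n_filters = 22, n_mfcc = 4),
      vte_stream = list(n_filters = 25, n_mfcc = 2),
      extras = c("F0", "F3"),
      decon = decon_config(36, 0.995),
      n_gaussians = 256, map_relevance = 24),
    abort(sprintf("Unknown preset '%s'.", name))
  )
}

#' Assembled per-utterance feature matrix
#'
#' @param values Matrix frames x dims.
#' @param layout Tibble with `slice`, `start`, `end`, `cepstral`.
#' @param vad_mask Logical per (pre-VAD) frame.
#' @param fp [frame_params()].
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, layout, vad_mask, fp) {
  stopifnot(is.matrix(values))
  if (nrow(layout) > 0 && layout$end[nrow(layout)] != ncol(values))
    abort("Layout slices must partition the dimension axis.")
  structure(list(values = values, layout = layout, vad_mask = vad_mask,
                 fp = fp),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d dims (%d/%d frames voiced)\n",
              nrow(x$values), ncol(x$values), sum(x$vad_mask),
              length(x$vad_mask)))
  cat("  slices:", paste(sprintf("%s[%d:%d]", x$layout$slice,
                                 x$layout$start, x$layout$end),
                         collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' Select feature slices by name
#'
#' Subsets the dimension axis of a [feature_matrix()] to the named
#' layout slices, preserving layout metadata. Used e.g. to derive a
#' speech-MFCC-only system from a full extended-biometric feature set.
#'
#' @param fm A `feature_matrix`.
#' @param slices Character vector of slice names to keep, in order.
#' @return A `feature_matrix` with the selected dimensions.
#' @export
select_streams <- function(fm, slices) {
  stopifnot(inherits(fm, "feature_matrix"))
  missing <- setdiff(slices, fm$layout$slice)
  if (length(missing))
    abort(paste("Unknown slices:", paste(missing, collapse = ", ")))
  keep <- fm$layout[match(slices, fm$layout$slice), ]
  cols <- unlist(Map(seq.int, keep$start, keep$end))
  widths <- keep$end - keep$start + 1L
  ends <- cumsum(widths)
  layout <- tibble(slice = keep$slice, start = c(1L, head(ends, -1L) + 1L),
                   end = ends, cepstral = keep$cepstral)
  feature_matrix(fm$values[, cols, drop = FALSE], layout, fm$vad_mask, fm$fp)
}

fill_unvoiced <- function(v, mode) {
  if (mode == "zero" || length(v) == 0L) return(v)
  voiced <- v > 0
  if (!any(voiced)) return(v)
  idx <- cummax(ifelse(voiced, seq_along(v), 0L))
  out <- ifelse(idx > 0L, v[pmax(idx, 1L)], 0)
  out
}

#' Assemble the per-gender feature matrix for one utterance
#'
#' The full front-end pipeline: denoising, source-tract deconstruction
#' (when GSE/VTE streams are configured), per-stream MFCC extraction with
#' speech-stream deltas, the extra features (E, dE, F0, F3), cepstral
#' mean subtraction, feature warping and RASTA filtering on the cepstral
#' slices, and finally the energy VAD mask (non-speech frames dropped).
#'
#' @param signal An `audio_signal`.
#' @param config A [gender_config()].
#' @return A [feature_matrix()].
#' @export
assemble_features <- function(signal, config) {
  stopifnot(inherits(signal, "audio_signal"),
            inherits(config, "gender_config"))
  fp <- config$fp
  x <- if (isTRUE(config$use_denoise)) denoise(signal) else signal

  need_decon <- !is.null(config$gse_stream) || !is.null(config$vte_stream)
  gse <- vte <- NULL
  if (need_decon) {
    dr <- deconstruct(x, config$decon)
    gse <- dr$gse; vte <- dr$vte
  }

  slices <- list(); cepstral <- logical(0)
  add_slice <- function(name, values, is_cepstral) {
    slices[[name]] <<- as.matrix(values)
    cepstral[name] <<- is_cepstral
  }

  sp <- config$speech_stream
  c_speech <- mfcc_stream(x, sp$n_filters, sp$n_mfcc, fp)
  add_slice("speech_mfcc", c_speech, TRUE)
  if (isTRUE(sp$use_delta)) add_slice("speech_delta", delta(c_speech), TRUE)
  if (isTRUE(sp$use_double_delta))
    add_slice("speech_ddelta", delta(delta(c_speech)), TRUE)
  if (!is.null(config$gse_stream))
    add_slice("gse_mfcc",
              mfcc_stream(gse, config$gse_stream$n_filters,
                          config$gse_stream$n_mfcc, fp), TRUE)
  if (!is.null(config$vte_stream))
    add_slice("vte_mfcc",
              mfcc_stream(vte, config$vte_stream$n_filters,
                          config$vte_stream$n_mfcc, fp), TRUE)

  n_frames <- nrow(c_speech)
  if ("E" %in% config$extras || "dE" %in% config$extras) {
    E <- frame_energy(x, fp)
    if ("E" %in% config$extras) add_slice("E", E, FALSE)
    if ("dE" %in% config$extras) add_slice("dE", delta(E), FALSE)
  }
  if ("F0" %in% config$extras) {
    f0 <- estimate_f0(x, fp, config$f0_range)
    f0 <- rep_len(f0, n_frames)
    add_slice("F0", fill_unvoiced(f0, config$unvoiced_fill), FALSE)
  }
  if ("F3" %in% config$extras) {
    f3 <- rep_len(estimate_f3(x, fp), n_frames)
    add_slice("F3", fill_unvoiced(f3, config$unvoiced_fill), FALSE)
  }

  widths <- unname(vapply(slices, ncol, integer(1)))
  ends <- cumsum(widths)
  layout <- tibble(slice = names(slices),
                   start = c(1L, head(ends, -1L) + 1L), end = ends,
                   cepstral = unname(cepstral[names(slices)]))
  values <- do.call(cbind, lapply(slices, unname))
  colnames(values) <- NULL

  mask <- energy_vad(x, fp)
  mask <- rep_len(mask, n_frames)
  values <- values[mask, , drop = FALSE]

  if (nrow(values) > 0L) {
    for (i in seq_len(nrow(layout))) {
      if (!layout$cepstral[i]) next
      cols <- layout$start[i]:layout$end[i]
      v <- cms(values[, cols, drop = FALSE])
      if (nrow(values) >= 3L) v <- feature_warp(v, config$warp_window)
      values[, cols] <- rasta(v)
    }
  }
  feature_matrix(values, layout, mask, fp)
}

#' Export / import a feature matrix as delimited text
#'
#' Self-describing: commented header lines carry the layout and frame
#' parameters; values are written at full precision so the round trip is
#' bit-exact.
#'
#' @param fm A [feature_matrix()].
#' @param path File path.
#' @return `path` invisibly (write); a `feature_matrix` (read).
#' @export
write_features <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#fp\t%g\t%g\t%s\t%d", fm$fp$frame_len_ms,
                     fm$fp$frame_shift_ms, fm$fp$window, fm$fp$fft_size), con)
  writeLines(paste0("#layout\t",
                    paste(sprintf("%s:%d:%d:%d", fm$layout$slice,
                                  fm$layout$start, fm$layout$end,
                                  as.integer(fm$layout$cepstral)),
                          collapse = "\t")), con)
  writeLines(paste0("#vad\t", paste(as.integer(fm$vad_mask), collapse = "")),
             con)
  if (nrow(fm$values) > 0L)
    writeLines(apply(fm$values, 1L,
                     function(r) paste(sprintf("%.17g", r), collapse = "\t")),
               con)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "\t")[[1L]]
  fp <- frame_params(as.numeric(hdr[2L]), as.numeric(hdr[3L]), hdr[4L],
                     as.integer(hdr[5L]))
  lay <- strsplit(lines[2L], "\t")[[1L]][-1L]
  parts <- strsplit(lay, ":")
  layout <- tibble(
    slice = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    cepstral = as.logical(as.integer(vapply(parts, `[`, "", 4L))))
  vad <- strsplit(sub("^#vad\t", "", lines[3L]), "")[[1L]] == "1"
  body <- lines[-(1:3)]
  values <- if (length(body)) {
    do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  } else {
    matrix(numeric(0), 0L, layout$end[nrow(layout)])
  }
  feature_matrix(values, layout, vad, fp)
}
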