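#' Diagonal-covariance Gaussian mixture container
#'
#' Doubles as the universal background model and as MAP-adapted speaker
#' models.
#'
#' @param weights Mixture weights (non-negative, sum 1).
#' @param means G x D matrix.
#' @param variances G x D matrix of diagonal variances (> 0).
#' @param meta Named list of metadata (gender, feature layout hash, ...).
#' @return Object of class `gmm_diag`.
#' @export
gmm_diag <- function(weights, means, variances, meta = list()) {
  means <- as.matrix(means); variances <- as.matrix(variances)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-10)
    abort("Weights must be non-negative and sum to 1.")
  if (!all(dim(means) == dim(variances)) || length(weights) != nrow(means))
    abort("Inconsistent mixture dimensions.")
  if (any(variances <= 0)) abort("Variances must be positive.")
  structure(list(weights = as.double(weights), means = means,
                 variances = variances, meta = meta),
            class = "gmm_diag")
}

#' @export
print.gmm_diag <- function(x, ...) {
  cat(sprintf("<gmm_diag> G = %d components, D = %d dims\n",
              length(x$weights), ncol(x$means)))
  invisible(x)
}

#' @describeIn gmm_diag One row per component: weight and mean norm.
#' @param x A `gmm_diag`.
#' @param ... Unused.
#' @export
tidy.gmm_diag <- function(x, ...) {
  tibble(component = seq_along(x$weights), weight = x$weights,
         mean_norm = sqrt(rowSums(x$means^2)),
         mean_variance = rowMeans(x$variances))
}

#' @describeIn gmm_diag One-row model summary.
#' @export
glance.gmm_diag <- function(x, ...) {
  tibble(n_components = length(x$weights), n_dims = ncol(x$means),
         log_lik = x$meta$final_loglik %||% NA_real_,
         n_iter = x$meta$n_iter %||% NA_integer_)
}

feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values
  else if (is.matrix(x)) x
  else if (is.list(x)) do.call(rbind, lapply(x, feature_values))
  else abort("Expected a feature matrix, a numeric matrix, or a list.")
}

# Per-frame per-component log densities: N x G.
gmm_log_components <- function(model, x) {
  D <- ncol(model$means)
  lognorm <- -0.5 * (D * log(2 * pi) + rowSums(log(model$variances)))
  inv <- 1 / model$variances
  # -(1/2) sum_d (x - mu)^2 / s2, expanded for matrix products
  q <- x^2 %*% t(inv / 2) - x %*% t(model$means * inv) +
    matrix(rowSums(model$means^2 * inv / 2), nrow(x), nrow(model$means),
           byrow = TRUE)
  sweep(-q, 2L, lognorm + log(model$weights), `+`)
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Per-frame mixture log-likelihoods
#'
#' @param model A [gmm_diag()].
#' @param features A [feature_matrix()], matrix, or list of either.
#' @return Numeric vector of per-frame log densities.
#' @export
gmm_loglik <- function(model, features) {
  x <- feature_values(features)
  if (nrow(x) == 0L) return(numeric(0))
  logsumexp_rows(gmm_log_components(model, x))
}

#' Train a universal background model by EM
#'
#' K-means-initialized expectation-maximization for a diagonal-covariance
#' Gaussian mixture, with a variance floor tied to the global
#' per-dimension variance. Stops at `max_iters` or when the relative
#' log-likelihood gain falls under `tol`. Deterministic given `seed`.
#' Components emptied during EM are re-seeded from the highest-weight
#' component.
#'
#' @param features Pooled training features (matrix, [feature_matrix()],
#'   or list of them).
#' @param G Number of components.
#' @param seed Integer seed.
#' @param max_iters Maximum EM iterations.
#' @param tol Relative log-likelihood stopping tolerance.
#' @param var_floor_frac Variance floor as a fraction of the global
#'   per-dimension variance.
#' @param kmeans_iters Iterations of the k-means initializer.
#' @param meta Metadata list stored on the model.
#' @return A [gmm_diag()]; per-iteration log-likelihoods in
#'   `meta$loglik_trace`.
#' @export
train_ubm <- function(features, G, seed = 1, max_iters = 50, tol = 1e-5,
                      var_floor_frac = 1e-3, kmeans_iters = 10,
                      meta = list()) {
  x <- feature_values(features)
  n <- nrow(x); D <- ncol(x)
  if (n <= G) abort("Need more frames than components.")
  gvar <- pmax(apply(x, 2L, var), 1e-12)
  floorv <- var_floor_frac * gvar

  withr::with_seed(seed, {
    km <- suppressWarnings(kmeans(x, centers = G, iter.max = kmeans_iters,
                                  nstart = 1L))
    means <- km$centers
    counts <- pmax(tabulate(km$cluster, G), 1)
    weights <- counts / sum(counts)
    variances <- matrix(gvar, G, D, byrow = TRUE)
    model <- gmm_diag(weights, means, variances)

    trace <- numeric(0)
    prev <- -Inf
    for (iter in seq_len(max_iters)) {
      lc <- gmm_log_components(model, x)
      ll_frame <- logsumexp_rows(lc)
      ll <- sum(ll_frame)
      resp <- exp(lc - ll_frame)                      # N x G
      nk <- colSums(resp)
      empty <- which(nk < 1e-8)
      if (length(empty)) {
        rlang::inform(sprintf(
          "EM: re-seeding %d empty component(s) from the heaviest component.",
          length(empty)))
        heavy <- which.max(nk)
        for (g in empty) {
          model$means[g, ] <- model$means[heavy, ] +
            rnorm(D, 0, sqrt(pmax(model$variances[heavy, ], floorv)) / 10)
          model$variances[g, ] <- model$variances[heavy, ]
          nk[g] <- 1
        }
        prev <- -Inf
        next
      }
      trace <- c(trace, ll)
      mu <- t(resp) %*% x / nk
      ex2 <- t(resp) %*% x^2 / nk
      s2 <- pmax(ex2 - mu^2, rep(floorv, each = G))
      model <- gmm_diag(nk / n, mu, s2)
      if (is.finite(prev) && (ll - prev) < tol * abs(ll)) break
      prev <- ll
    }
    model$meta <- c(meta, list(loglik_trace = trace,
                               final_loglik = tail(trace, 1L),
                               n_iter = length(trace), seed = seed,
                               var_floor = floorv))
    model
  })
}

#' MAP mean adaptation of a speaker model from the UBM
#'
#' Only the component means are adapted:
#' `mu_k <- (n_k E_k + alpha m_k) / (n_k + alpha)` with `n_k` the soft
#' count and `E_k` the posterior-weighted data mean; weights and
#' variances are copied unchanged from the UBM.
#'
#' @param ubm A [gmm_diag()] universal background model.
#' @param features Enrollment features.
#' @param relevance MAP relevance factor alpha (>= 0).
#' @param meta Metadata stored on the adapted model.
#' @return A [gmm_diag()] speaker model.
#' @export
map_adapt <- function(ubm, features, relevance, meta = list()) {
  stopifnot(inherits(ubm, "gmm_diag"))
  if (relevance < 0) abort("`relevance` must be >= 0.")
  x <- feature_values(features)
  if (ncol(x) != ncol(ubm$means))
    abort("Feature dimension does not match the UBM layout.")
  if (nrow(x) == 0L) abort("No frames available for MAP adaptation.")
  lc <- gmm_log_components(ubm, x)
  resp <- exp(lc - logsumexp_rows(lc))
  nk <- colSums(resp)
  ek <- t(resp) %*% x / pmax(nk, 1e-300)
  denom <- nk + relevance
  wgt <- ifelse(denom > 0, nk / pmax(denom, 1e-300), 0)
  means <- ubm$means + wgt * (ek - ubm$means)
  means[nk <= 0 & relevance == 0, ] <- ubm$means[nk <= 0 & relevance == 0, ]
  gmm_diag(ubm$weights, means, ubm$variances,
           meta = c(meta, list(adapted_from_ubm = TRUE,
                               relevance = relevance, soft_counts = nk)))
}

#' Log-likelihood-ratio trial score
#'
#' The mean per-frame difference between the speaker-model and UBM log
#' densities over the (VAD-passed) frames of the test segment; the
#' `"sum"` aggregate is available as an option.
#'
#' @param speaker,ubm [gmm_diag()] models sharing a feature layout.
#' @param features Test-segment features.
#' @param aggregate `"mean"` (duration-comparable, default) or `"sum"`.
#' @return The scalar LLR score.
#' @export
llr_score <- function(speaker, ubm, features, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  x <- feature_values(features)
  if (nrow(x) == 0L)
    abort("Scoring error: no frames to score (empty test segment).")
  d <- gmm_loglik(speaker, x) - gmm_loglik(ubm, x)
  if (aggregate == "mean") mean(d) else sum(d)
}
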