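two_clusters <- function(n = 600, d = 4, sep = 8, seed = 1) {
  withr::with_seed(seed, {
    x1 <- matrix(rnorm(n * d), ncol = d)
    x2 <- matrix(rnorm(n * d), ncol = d)
    x2[, 1] <- x2[, 1] + sep
    rbind(x1, x2)
  })
}

test_that("EM recovers well-separated clusters", {
  x <- two_clusters(n = 3000)
  m <- train_ubm(x, G = 2, seed = 5)
  centers <- m$means[order(m$means[, 1]), ]
  expect_lt(max(abs(centers[1, ] - c(0, 0, 0, 0))), 0.05)
  expect_lt(max(abs(centers[2, ] - c(8, 0, 0, 0))), 0.05)
  expect_equal(sum(m$weights), 1, tolerance = 1e-10)
})

test_that("EM log-likelihood is non-decreasing and seeded runs agree", {
  x <- two_clusters(seed = 2)
  m1 <- train_ubm(x, G = 4, seed = 7)
  trace <- m1$meta$loglik_trace
  expect_gte(min(diff(trace)), -1e-8)
  m2 <- train_ubm(x, G = 4, seed = 7)
  expect_identical(m1$means, m2$means)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_ubm(x, G = 4, seed = 8)
  expect_false(identical(m1$means, m3$means))
})

test_that("gmm_diag validates its invariants", {
  expect_error(gmm_diag(c(0.5, 0.4), matrix(0, 2, 2), matrix(1, 2, 2)),
               "sum to 1")
  expect_error(gmm_diag(c(0.5, 0.5), matrix(0, 2, 2), matrix(0, 2, 2)),
               "positive")
  expect_error(train_ubm(matrix(rnorm(10), 5, 2), G = 8), "more frames")
})

test_that("MAP adaptation obeys its limit laws and stays on the segment", {
  x <- two_clusters(n = 300, seed = 3)
  ubm <- train_ubm(x, G = 4, seed = 1)
  withr::with_seed(4, feats <- x[sample(nrow(x), 200), ] + 0.5)

  huge <- map_adapt(ubm, feats, relevance = 1e9)
  expect_lt(max(abs(huge$means - ubm$means)), 1e-6)

  zero <- map_adapt(ubm, feats, relevance = 0)
  # two-pass oracle: posterior-weighted data means
  lc <- sourcetract:::gmm_log_components(ubm, feats)
  resp <- exp(lc - apply(lc, 1, function(r) max(r) + log(sum(exp(r - max(r))))))
  ek <- t(resp) %*% feats / colSums(resp)
  expect_lt(max(abs(zero$means - ek)), 1e-10)

  mid <- map_adapt(ubm, feats, relevance = 16)
  # adapted means lie between UBM means and data means, elementwise
  lo <- pmin(ubm$means, ek) - 1e-12
  hi <- pmax(ubm$means, ek) + 1e-12
  expect_true(all(mid$means >= lo & mid$means <= hi))
  expect_identical(mid$weights, ubm$weights)
  expect_identical(mid$variances, ubm$variances)
  expect_error(map_adapt(ubm, feats[, 1:2], 16), "dimension")
})

test_that("LLR scoring matches closed forms and separates speakers", {
  # identical models score exactly zero
  ubm <- train_ubm(two_clusters(n = 200, seed = 6), G = 2, seed = 1)
  withr::with_seed(7, test <- matrix(rnorm(50 * 4), ncol = 4))
  expect_identical(llr_score(ubm, ubm, test), 0)

  # single-component mixtures: closed-form Gaussian log-density ratio
  m1 <- gmm_diag(1, matrix(c(0, 0), 1), matrix(c(1, 2), 1))
  m2 <- gmm_diag(1, matrix(c(1, -1), 1), matrix(c(2, 1), 1))
  withr::with_seed(8, x <- matrix(rnorm(40), ncol = 2))
  ld <- function(x, mu, s2)
    rowSums(dnorm(x, mean = rep(mu, each = nrow(x)),
                  sd = rep(sqrt(s2), each = nrow(x)), log = TRUE))
  oracle <- mean(ld(x, c(0, 0), c(1, 2)) - ld(x, c(1, -1), c(2, 1)))
  expect_lt(abs(llr_score(m1, m2, x) - oracle), 1e-10)
  expect_equal(llr_score(m1, m2, x, aggregate = "sum"),
               llr_score(m1, m2, x) * nrow(x))
  expect_error(llr_score(m1, m2, x[0, , drop = FALSE]), "Scoring error")

  # draws from an adapted model score higher against it than an impostor
  x <- two_clusters(n = 400, seed = 9)
  ubm <- train_ubm(x, G = 4, seed = 2)
  own <- map_adapt(ubm, x[1:200, ] + 0.3, 4)
  imp <- map_adapt(ubm, x[601:800, ] - 0.3, 4)
  wins <- withr::with_seed(10, {
    vapply(1:20, function(i) {
      draw <- x[sample(200, 60), ] + 0.3 + matrix(rnorm(240, 0, 0.1), 60)
      llr_score(own, ubm, draw) > llr_score(imp, ubm, draw)
    }, logical(1))
  })
  expect_gt(mean(wins), 0.5)
})

test_that("Z-norm standardizes scores by impostor statistics", {
  expect_equal(znorm(2.0, list(mu = 1.0, sigma = 0.5)), 2.0)
  expect_equal(znorm(1.7, list(mu = 0, sigma = 1)), 1.7)
  expect_error(znorm(1, list(mu = 0, sigma = 0)), "Normalization error")

  x <- two_clusters(n = 200, seed = 11)
  ubm <- train_ubm(x, G = 2, seed = 3)
  model <- map_adapt(ubm, x[1:100, ], 8)
  withr::with_seed(12, cohort <- lapply(1:6, function(i)
    matrix(rnorm(160, sd = 1.3), ncol = 4)))
  zs <- znorm_stats(model, ubm, cohort)
  raw <- vapply(cohort, function(f) llr_score(model, ubm, f), numeric(1))
  normed <- znorm(raw, zs)
  expect_lt(abs(mean(normed)), 1e-10)
  expect_lt(abs(sd(normed) - 1), 1e-10)
  expect_error(znorm_stats(model, ubm, cohort[1]), ">= 2")
})

test_that("T-norm mirrors Z-norm with roles swapped", {
  x <- two_clusters(n = 200, seed = 13)
  ubm <- train_ubm(x, G = 2, seed = 4)
  withr::with_seed(14, test <- matrix(rnorm(120), ncol = 4))
  models <- lapply(1:6, function(i)
    map_adapt(ubm, x[((i - 1) * 50 + 1):(i * 50), ], 4))
  ts <- tnorm_stats(test, models, ubm)
  # hand-composed two-step oracle
  cs <- vapply(models, function(m) llr_score(m, ubm, test), numeric(1))
  raw <- 0.42
  expect_lt(abs(tnorm(raw, ts) - (raw - mean(cs)) / sd(cs)), 1e-12)
  expect_error(tnorm_stats(test, models[1], ubm), ">= 2")
  expect_error(tnorm_stats(test, list(models[[1]], models[[1]]), ubm),
               "degenerate")
  # ZT-norm composes Z-norm first
  zstats <- list(mu = 0.1, sigma = 2)
  expect_equal(ztnorm(raw, zstats, ts),
               tnorm(znorm(raw, zstats), ts))
})
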