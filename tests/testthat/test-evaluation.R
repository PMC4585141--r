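brute_rates <- function(th, tgt, non) {
  c(far = 100 * sum(non >= th) / length(non),
    frr = 100 * sum(tgt < th) / length(tgt))
}

test_that("error curves count FAR/FRR exhaustively", {
  cv <- error_curve(c(2, 3), c(0, 1))
  at <- function(th) unlist(cv[which.min(abs(cv$threshold - th)), 2:3])
  r <- brute_rates(1.5, c(2, 3), c(0, 1))
  expect_equal(unname(r), c(0, 0))
  expect_equal(eer_and_threshold(cv)$eer, 0)
  expect_error(error_curve(numeric(0), 1), "non-empty")
})

test_that("FAR + FRR is 100 for identical score populations", {
  withr::with_seed(1, s <- round(rnorm(40), 1))
  cv <- error_curve(s, s)
  inner <- cv$threshold > min(s) & cv$threshold <= max(s)
  expect_true(all(abs(cv$far[inner] + cv$frr[inner] - 100) < 1e-12))
})

test_that("curve monotonicity holds on random score sets", {
  withr::with_seed(2, {
    for (i in 1:200) {
      tgt <- rnorm(sample(1:30, 1), mean = runif(1, -1, 2))
      non <- rnorm(sample(1:30, 1))
      cv <- error_curve(tgt, non)
      expect_true(all(diff(cv$far) <= 0))
      expect_true(all(diff(cv$frr) >= 0))
      expect_true(all(cv$far >= 0 & cv$far <= 100))
      expect_true(all(cv$frr >= 0 & cv$frr <= 100))
    }
  })
})

test_that("EER matches exhaustive threshold enumeration", {
  # interleaved classes: one of each class is misclassified at any
  # threshold between the middle scores, so counting (not ROC
  # interpolation) gives FAR = FRR = 50 there
  tgt <- c(1, 3); non <- c(0, 2)
  cv <- error_curve(tgt, non)
  op <- eer_and_threshold(cv)
  # brute-force oracle over a dense grid
  grid <- seq(-1, 4, by = 0.01)
  rates <- t(vapply(grid, brute_rates, numeric(2), tgt, non))
  best <- which.min(abs(rates[, 1] - rates[, 2]))
  expect_equal(op$eer, mean(rates[best, ]))
  expect_equal(op$eer, 50)
  # well-separated classes with one overlap: EER = 25 by counting
  op2 <- eer_and_threshold(error_curve(c(1, 3, 4, 5), c(0, 0.5, 0.6, 2)))
  expect_equal(op2$eer, 25)
})

test_that("EER of exchangeable scores is 50 percent", {
  withr::with_seed(3, {
    cv <- error_curve(rnorm(10000), rnorm(10000))
    eer <- eer_and_threshold(cv)$eer
    expect_gte(eer, 48); expect_lte(eer, 52)
  })
})

test_that("EER is invariant under strictly increasing transforms", {
  withr::with_seed(4, {
    tgt <- rnorm(200, 1); non <- rnorm(300)
    e1 <- eer_and_threshold(error_curve(tgt, non))$eer
    f <- function(x) exp(x) + x^3
    e2 <- eer_and_threshold(error_curve(f(tgt), f(non)))$eer
    expect_equal(e1, e2)
  })
})

test_that("label swap maps the EER to its complement", {
  withr::with_seed(5, {
    tgt <- rnorm(150, 0.8); non <- rnorm(250)
    e <- eer_and_threshold(error_curve(tgt, non))$eer
    # swapped labels on the same scores: FAR and FRR trade places as
    # complements, so the EER maps to 100 - EER
    e_swap <- eer_and_threshold(error_curve(non, tgt))$eer
    expect_equal(e_swap, 100 - e)
  })
})

test_that("HTER is the frozen-threshold mean of FAR and FRR", {
  withr::with_seed(6, {
    tgt <- rnorm(100, 2); non <- rnorm(100)
    th <- 1.0
    r <- brute_rates(th, tgt, non)
    expect_equal(hter(tgt, non, th), mean(r))
    expect_equal(hter(tgt, non, min(c(tgt, non)) - 1), 50)
    op <- eer_and_threshold(error_curve(tgt, non))
    expect_equal(hter(tgt, non, op$threshold), op$eer)
  })
})

test_that("HEER and relative reduction reproduce the printed arithmetic", {
  expect_equal(round(heer(2.534, 2.170), 3), 2.352)
  expect_equal(round(heer(11.567, 11.693), 3), 11.630)
  expect_equal(heer(7.3, 7.3), 7.3)
  expect_equal(round(relative_reduction(2.534, 2.390), 2), 5.68)
  expect_equal(round(relative_reduction(2.534, 1.504), 2), 40.65)
  expect_equal(relative_reduction(3, 3), 0)
  expect_lt(relative_reduction(2, 3), 0)
})

test_that("DET coordinates are finite double-probit transforms", {
  withr::with_seed(7, {
    tgt <- rnorm(50, 3); non <- rnorm(50)
    dp <- det_points(error_curve(tgt, non))
    expect_true(all(is.finite(dp$det_far)))
    expect_true(all(is.finite(dp$det_frr)))
  })
  cv <- error_curve(c(0, 1), c(0, 1))
  dp <- det_points(cv)
  i <- which(cv$far == 50 & cv$frr == 50)
  expect_equal(dp$det_far[i], 0)
  expect_equal(dp$det_frr[i], 0)
  # symmetric populations give DET points symmetric about the diagonal
  withr::with_seed(8, {
    a <- rnorm(4000)
    cv2 <- error_curve(a, -a)
    dp2 <- det_points(cv2)
    i50 <- which.min(abs(cv2$far - 50))
    expect_lt(abs(dp2$det_far[i50] + 0) + abs(dp2$det_frr[i50] - 0), 0.1)
  })
  p <- autoplot(error_curve(rnorm(20, 1), rnorm(20)))
  expect_s3_class(p, "ggplot")
})

test_that("two-layer bootstrap SE behaves like the analytic SE", {
  withr::with_seed(9, {
    n <- 200
    scores <- tibble::tibble(
      speaker = c(paste0("t", 1:n), paste0("n", 1:n)),
      score = c(rnorm(n, 1), rnorm(n, -1)),
      label = rep(c("target", "nontarget"), each = n))
    th <- 0
    bs <- bootstrap_se_dcf(scores, th, n_reps = 2000, seed = 1)
    p1 <- mean(scores$score[scores$label == "target"] < th)
    p2 <- mean(scores$score[scores$label == "nontarget"] >= th)
    analytic <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
    expect_lt(abs(bs$se - analytic) / analytic, 0.15)
    expect_identical(bs$se,
                     bootstrap_se_dcf(scores, th, n_reps = 2000, seed = 1)$se)
  })
  const <- tibble::tibble(speaker = rep(c("a", "b", "c", "d"), 2),
                          score = 1,
                          label = rep(c("target", "nontarget"), each = 4))
  expect_equal(bootstrap_se_dcf(const, 0.5, n_reps = 50, seed = 2)$se, 0)
  one <- tibble::tibble(speaker = c("a", "a", "b", "c"),
                        score = rnorm(4),
                        label = c("target", "target", "nontarget",
                                  "nontarget"))
  expect_error(bootstrap_se_dcf(one, 0, n_reps = 10, seed = 3), ">= 2")
})
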