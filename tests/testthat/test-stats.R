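test_that("empty subfamily draws give p = 1 and invalid counts refuse", {
  expect_equal(hypergeom_pvalue(10, 2, 0, 1, 0, 6), 1)
  expect_error(hypergeom_pvalue(10, 11, 1, 1, 1, 6), "n_pred_super")
  expect_error(hypergeom_pvalue(10, 2, 1, -1, 1, 6), "non-negative")
  expect_error(hypergeom_pvalue(40, 2, 1, 1, 1, 6), "L\\^2")
})

test_that("the enrichment sum matches independent closed-form evaluation", {
  # small worked case against the hypergeometric upper tail: with default
  # totals the printed sum is P(X >= n_pred_sub) for
  # X ~ Hypergeom(A + B, A, k)
  p <- hypergeom_pvalue(10, 2, 4, 1, 3, 6)
  A <- 10 - 2
  B <- (36 - 10) - 1
  p_ref <- stats::phyper(4 - 1, A, B, 4 + 3, lower.tail = FALSE)
  expect_equal(p, p_ref, tolerance = 1e-12)

  set.seed(51)
  for (rep in 1:50) {
    L <- sample(5:14, 1)
    n_exp <- sample(1:min(150, L^2 - 1), 1)
    nps <- sample(0:n_exp, 1)
    nns <- sample(0:min(40, L^2 - n_exp), 1)
    npd <- sample(0:40, 1)
    nnd <- sample(0:40, 1)
    A <- n_exp - nps
    B <- (L^2 - n_exp) - nns
    k <- npd + nnd
    if (k > A + B) next
    p1 <- hypergeom_pvalue(n_exp, nps, npd, nns, nnd, L)
    p2 <- stats::phyper(npd - 1, A, B, k, lower.tail = FALSE)
    expect_equal(p1, min(p2, 1), tolerance = 1e-9)
  }
})

test_that("more correct subfamily contacts never weaken the evidence", {
  for (npd in 0:12) {
    p_lo <- hypergeom_pvalue(30, 5, npd, 2, 6, 8)
    p_hi <- hypergeom_pvalue(30, 5, npd + 1, 2, 6, 8)
    expect_lte(p_hi, p_lo + 1e-15)
  }
  # p stays a probability over consistent small count vectors
  set.seed(53)
  for (rep in 1:100) {
    L <- sample(6:9, 1)
    n_exp <- sample(5:30, 1)
    nps <- sample(0:4, 1)
    nns <- sample(0:4, 1)
    npd <- sample(0:min(10, n_exp - nps), 1)
    nnd <- sample(0:min(10, L^2 - n_exp - nns), 1)
    p <- hypergeom_pvalue(n_exp, nps, npd, nns, nnd, L)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("Epps-Singleton reproduces reference values and detects shifts", {
  # expected values computed once with an independent implementation of
  # the published test (empirical characteristic function at t = .4/.8
  # over the pooled semi-IQR, biased covariances, small-sample correction)
  x <- c(1.2, 2.3, 0.5, 3.1, 2.2, 1.8, 0.9, 2.5, 3.3, 1.1)
  y <- c(2.2, 3.3, 1.5, 4.1, 3.2, 2.8, 1.9, 3.5, 4.3, 2.1, 5.0, 0.3)
  r <- epps_singleton(x, y)
  expect_equal(unname(r$statistic), 3.5923413659, tolerance = 1e-9)
  expect_equal(r$p.value, 0.4639772236, tolerance = 1e-9)
  expect_equal(unname(r$parameter), 4)

  x2 <- seq(0, 5, length.out = 40)
  y2 <- c(seq(0.2, 4, length.out = 30), 9, 11, 12, 14, 15, 16, 17, 18,
          19, 20)
  r2 <- epps_singleton(x2, y2)
  expect_equal(unname(r2$statistic), 12.0718520554, tolerance = 1e-9)

  # gross separation: sample vs itself shifted by 10 pooled IQRs
  set.seed(55)
  a <- rnorm(50)
  b <- a + 10 * stats::IQR(c(a, a))
  expect_lt(epps_singleton(a, b)$p.value, 0.001)

  # affine invariance of the standardized statistic
  w1 <- unname(epps_singleton(x, y)$statistic)
  w2 <- unname(epps_singleton(3 * x + 7, 3 * y + 7)$statistic)
  expect_equal(w1, w2, tolerance = 1e-10)

  expect_error(epps_singleton(rep(1, 10), rep(1, 12)), "interquartile")
  expect_error(epps_singleton(1:4, 1:10), "at least 5")
})

test_that("non-dominant fraction complements the dominant+common share", {
  dm <- toy_dualmap12()
  dm$dominant_id <- "a"
  all_dom <- data.frame(i = c(1, 2, 3), j = c(5, 6, 9))
  c0 <- categorize_predictions(all_dom, dm)
  expect_equal(nondominant_fraction(c0), 0)
  mixed <- data.frame(i = c(7, 7, 7, 8, 1, 3, 4, 2, 10, 9),
                      j = c(11, 13, 9, 12, 5, 9, 9, 4, 12, 11))
  cm <- categorize_predictions(mixed, dm)
  nd <- nondominant_fraction(cm)
  expect_equal(nd, (nrow(cm$alternative) + nrow(cm$unobserved)) / 10)
  expect_equal(nd, 1 - (nrow(cm$dominant) + nrow(cm$common)) / 10)
  empty <- categorize_predictions(all_dom[0, ], dm)
  expect_error(nondominant_fraction(empty), "no predictions")
})

test_that("amplification is a plain percent increase over the baseline", {
  expect_equal(amplification(10, 30), 200)
  expect_equal(amplification(7, 7), 0)
  expect_warning(a <- amplification(0, 5), "undefined")
  expect_true(is.na(a))
})

test_that("depth fractions floor into 0.05-wide bins capped at 0.95", {
  expect_equal(depth_bin(19050, 20000), 0.95)
  expect_equal(depth_bin(999, 20000), 0)
  expect_equal(depth_bin(20000, 20000), 0.95)
  expect_equal(depth_bin(1, 20000), 0)
  expect_equal(depth_bin(c(1000, 1999, 10000), 20000),
               c(0.05, 0.05, 0.50))
  expect_error(depth_bin(0, 100))
  expect_error(depth_bin(101, 100))
})

test_that("enhancement profiles accumulate from deep to shallow bins", {
  # deep alignment (bin 0.95) predicts one contact; the shallowest (bin
  # 0.00) adds two more: counts are 3 at bin 0.00 and 1 elsewhere, so
  # z peaks at the shallow end: z(0.00) = 1.9/sqrt(0.19)
  sets <- list(data.frame(i = 1, j = 9),
               data.frame(i = c(1, 2, 3), j = c(9, 12, 13)))
  prof <- enhancement_profile(sets, depths = c(20000, 999),
                              superfamily_depth = 20000)
  expect_equal(unname(prof$counts[, 1]), c(3L, rep(1L, 19)))
  expect_equal(unname(prof$z[1, 1]), 1.9 / sqrt(0.19), tolerance = 1e-12)
  expect_equal(unname(prof$z[2, 1]), -0.1 / sqrt(0.19), tolerance = 1e-12)
  expect_equal(mean(prof$z[, 1]), 0, tolerance = 1e-12)
  expect_true(all(diff(prof$counts[, 1]) <= 0))

  # identical predictions everywhere -> flat profile, all z zero
  flat <- enhancement_profile(list(data.frame(i = 1, j = 9),
                                   data.frame(i = 1, j = 9)),
                              depths = c(20000, 999),
                              superfamily_depth = 20000)
  expect_true(all(flat$z == 0))

  # a single populated bin has no variance to standardize
  expect_error(enhancement_profile(sets, depths = c(20000, 19500),
                                   superfamily_depth = 20000),
               "zero variance")

  # named categories and cohort medians
  sets2 <- list(list(alternative = data.frame(i = 1, j = 9)),
                list(alternative = data.frame(i = c(1, 5), j = c(9, 20))))
  p2 <- enhancement_profile(sets2, c(20000, 999), 20000)
  med <- profile_medians(list(p2, p2))
  expect_equal(dim(med), c(20L, 1L))
  expect_equal(med[, "alternative"], p2$z[, "alternative"])
})
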