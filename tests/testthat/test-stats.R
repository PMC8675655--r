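test_that("signed-rank exact p matches brute-force enumeration exhaustively", {
  # all sign patterns on untied magnitudes, n = 3..8
  for (n in 3:8) {
    mags <- seq_len(n) + 0.1 * seq_len(n)^2  # untied, irregular spacing
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    for (i in seq_len(nrow(signs))) {
      d <- mags * signs[i, ]
      res <- wilcoxon_signed_rank(d)
      expect_identical(res$method, "exact")
      expect_equal(res$p_value, oracle_signed_rank_p(d))
    }
  }
})

test_that("signed-rank exact p matches stats::wilcox.test on random pairs", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("U-test exact p matches brute-force enumeration exhaustively", {
  set.seed(7)
  for (n1 in 2:5) for (n2 in 2:(8 - n1)) {
    for (rep in 1:4) {
      x <- rnorm(n1); y <- rnorm(n2)
      res <- mann_whitney_u(x, y)
      expect_identical(res$method, "exact")
      expect_equal(res$p_value, oracle_mwu_p(x, y))
    }
  }
})

test_that("worked small-sample values are reproduced", {
  # six positive differences: two-sided exact p = 2/2^6
  res <- one_sample_wilcoxon(c(1.2, 1.3, 1.1, 1.4, 1.25, 1.15), mu0 = 1)
  expect_equal(res$p_value, 0.03125)
  expect_identical(res$method, "exact")
  # complete separation at n1 = n2 = 3: U = 0, p = 2/choose(6,3)
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  # textbook t interval for 1..5
  ci <- mean_ci(1:5)
  expect_equal(as.numeric(ci), c(1.036757, 4.963243), tolerance = 1e-6)
})

test_that("test symmetries and identities hold", {
  set.seed(11)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(y, x)$p_value)
  # translation invariance of the one-sample test
  v <- rnorm(9) + 1
  expect_equal(one_sample_wilcoxon(v, 1)$p_value,
               one_sample_wilcoxon(v + 5, 6)$p_value)
  # values exactly symmetric about mu0: two-sided exact p = 1
  v <- c(1 - c(0.3, 0.2, 0.1), 1 + c(0.3, 0.2, 0.1))
  expect_equal(one_sample_wilcoxon(v, 1)$p_value, 1)
  # U_x + U_y = n1 * n2, including with ties
  a <- sample(1:5, 9, TRUE); b <- sample(1:5, 14, TRUE)
  expect_equal(mann_whitney_u(a, b)$statistic +
                 mann_whitney_u(b, a)$statistic, 9 * 14)
})

test_that("degenerate inputs error and ties fall through to the approximation", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "nonzero")
  expect_error(one_sample_wilcoxon(rep(2, 6), 2), "undefined")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  expect_error(mean_ci(3), "at least 2")
  expect_equal(as.numeric(mean_ci(rep(4, 10))), c(4, 4))
  # tied magnitudes cannot be enumerated exactly
  res <- wilcoxon_signed_rank(c(3, 3, -3, 5, 6, -7, 8, 1))
  expect_identical(res$method, "approximate")
  res <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4))
  expect_identical(res$method, "approximate")
  # zero differences are dropped and reported
  res <- wilcoxon_signed_rank(c(0, 0, 1.2, -2.1, 0.6, 1.9))
  expect_match(res$note, "2 zero difference")
  expect_equal(res$n, 4)
})

test_that("approximate p-values match wilcox.test's tie-corrected form", {
  set.seed(23)
  for (i in 1:25) {
    x <- sample(1:6, 20, TRUE); y <- sample(1:6, 20, TRUE)
    d <- x - y
    if (sum(d != 0) < 2 || all(d[d != 0] > 0) || all(d[d != 0] < 0)) next
    expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                 suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE)$p.value))
    a <- sample(1:8, 15, TRUE); b <- sample(1:8, 17, TRUE)
    expect_equal(mann_whitney_u(a, b)$p_value,
                 suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value))
  }
})

test_that("rejection rate under the null is close to nominal for both tests", {
  set.seed(31)
  n_sim <- 2000
  rej_sr <- rej_mw <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    x <- rnorm(10); y <- rnorm(10)
    rej_sr[i] <- wilcoxon_signed_rank(x, y)$p_value < 0.05
    rej_mw[i] <- mann_whitney_u(rnorm(6), rnorm(6))$p_value < 0.05
  }
  expect_gte(mean(rej_sr), 0.03); expect_lte(mean(rej_sr), 0.075)
  expect_gte(mean(rej_mw), 0.03); expect_lte(mean(rej_mw), 0.075)
})

test_that("t confidence interval attains nominal coverage", {
  set.seed(41)
  cover <- vapply(1:2000, function(i) {
    ci <- mean_ci(rnorm(12, mean = 3))
    ci[["lower"]] <= 3 && 3 <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})
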