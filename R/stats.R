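#' Nonparametric test toolkit
#'
#' Exact small-sample implementations of the two-sided Wilcoxon
#' matched-pairs signed-rank test, the one-sample Wilcoxon signed-rank test
#' and the Mann-Whitney U test, the three tests used for all per-disc
#' comparisons. Exact p-values are obtained by enumeration (all `2^n` sign
#' assignments for the signed-rank statistic, all `choose(n1+n2, n1)` rank
#' splits for the U statistic) whenever the sample is inside the exact
#' bound and free of ties; otherwise a tie-corrected normal approximation
#' with continuity correction is used and recorded in `method`. No
#' multiple-comparison correction is applied anywhere.
#'
#' @name disc_tests
NULL

new_test_result <- function(test_name, statistic, p_value, n, sidedness,
                            method, note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = min(p_value, 1), n = n, sidedness = sidedness,
                 method = method, note = note),
            class = "dq_test")
}

#' @export
print.dq_test <- function(x, ...) {
  cat(sprintf("%s (%s, %s): statistic = %.4g, p = %.4g, n = %s\n",
              x$test_name, x$sidedness, x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# exact null distribution of the signed-rank statistic for given |d| ranks:
# enumerate all 2^n sign assignments (cached per rank multiset)
.signrank_cache <- new.env(parent = emptyenv())
signrank_null <- function(ranks) {
  key <- paste0(ranks, collapse = ",")
  got <- .signrank_cache[[key]]
  if (!is.null(got)) return(got)
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% ranks)
  .signrank_cache[[key]] <- w
  w
}

two_sided_exact_p <- function(null_values, observed) {
  lo <- mean(null_values <= observed + 1e-9)
  hi <- mean(null_values >= observed - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' @param x,y paired measurements (`y` omitted for a pre-computed vector of
#'   differences tested against zero). Pairs with zero difference are
#'   dropped, Wilcoxon-style, and counted in the result's `note`.
#' @param two_sided if `FALSE`, the alternative is `x > y` (one-sided).
#' @param exact_limit largest n for which the exact sign-assignment
#'   enumeration is used (requires untied absolute differences).
#' @return a `dq_test` with the signed-rank statistic (sum of ranks of
#'   positive differences), p-value, n used, and method (`exact` or
#'   `approximate`).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, two_sided = TRUE,
                                 exact_limit = 15L) {
  if (is.null(y)) y <- rep(0, length(x))
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L) stop("no nonzero pairs (need >= 2 nonzero differences)")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  tied <- anyDuplicated(abs(d)) > 0L
  note <- if (n_zero) sprintf("%d zero difference(s) dropped", n_zero) else NULL
  if (n <= exact_limit && !tied) {
    p <- if (two_sided) two_sided_exact_p(signrank_null(r), w)
         else mean(signrank_null(r) >= w - 1e-9)
    return(new_test_result("wilcoxon_signed_rank", w, p, n,
                           if (two_sided) "two-sided" else "greater",
                           "exact", note))
  }
  # normal approximation with tie correction and continuity correction
  mu <- n * (n + 1) / 4
  tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  z <- w - mu
  cc <- sign(z) * 0.5
  z <- (z - cc) / sqrt(sigma2)
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
  new_test_result("wilcoxon_signed_rank", w, min(1, p), n,
                  if (two_sided) "two-sided" else "greater",
                  "approximate", note)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether values are symmetric about `mu0` (used for P/A ratios
#' against 1).
#'
#' @param values numeric vector.
#' @param mu0 null center.
#' @inheritParams wilcoxon_signed_rank
#' @return a `dq_test`.
#' @export
one_sample_wilcoxon <- function(values, mu0 = 0, two_sided = TRUE,
                                exact_limit = 15L) {
  if (all(values == mu0)) stop("all values equal mu0; test undefined")
  out <- wilcoxon_signed_rank(values, rep(mu0, length(values)),
                              two_sided = two_sided, exact_limit = exact_limit)
  out$test_name <- "one_sample_wilcoxon"
  out
}

# exact null distribution of U via enumeration of rank splits (cached by n1,n2)
.mwu_cache <- new.env(parent = emptyenv())
mwu_null <- function(n1, n2) {
  key <- paste(n1, n2)
  got <- .mwu_cache[[key]]
  if (!is.null(got)) return(got)
  splits <- combn(n1 + n2, n1)
  # U = sum of x-ranks - n1(n1+1)/2 for each split of pooled ranks
  u <- colSums(splits) - n1 * (n1 + 1) / 2
  .mwu_cache[[key]] <- u
  u
}

#' Mann-Whitney U test
#'
#' @param x,y the two unpaired groups.
#' @param two_sided if `FALSE`, the alternative is a shift `x > y`.
#' @param exact_limit largest `n1 + n2` for which the exact rank-split
#'   enumeration is used (requires no cross-group ties).
#' @return a `dq_test`; the statistic is `U` for group `x` (number of
#'   `(x, y)` pairs with `x > y`, ties counting one half).
#' @export
mann_whitney_u <- function(x, y, two_sided = TRUE, exact_limit = 12L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tied <- anyDuplicated(pooled) > 0L
  if (n1 + n2 <= exact_limit && !tied) {
    nullu <- mwu_null(n1, n2)
    p <- if (two_sided) two_sided_exact_p(nullu, u)
         else mean(nullu >= u - 1e-9)
    return(new_test_result("mann_whitney_u", u, p, c(n1, n2),
                           if (two_sided) "two-sided" else "greater", "exact"))
  }
  mu <- n1 * n2 / 2
  tab <- table(r)
  nn <- n1 + n2
  sigma2 <- (n1 * n2 / 12) * ((nn + 1) - sum(tab^3 - tab) / (nn * (nn - 1)))
  if (sigma2 <= 0)  # all pooled values tied: no rank information
    return(new_test_result("mann_whitney_u", u, 1, c(n1, n2),
                           if (two_sided) "two-sided" else "greater",
                           "approximate", note = "all values tied"))
  z <- u - mu
  cc <- sign(z) * 0.5
  z <- (z - cc) / sqrt(sigma2)
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
  new_test_result("mann_whitney_u", u, min(1, p), c(n1, n2),
                  if (two_sided) "two-sided" else "greater", "approximate")
}

#' Student-t confidence interval of the mean
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level.
#' @return named numeric `c(lower, upper)` with attribute `mean`. A constant
#'   vector yields a zero-width interval at the constant.
#' @export
mean_ci <- function(values, level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a confidence interval")
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  out <- c(lower = m - half, upper = m + half)
  attr(out, "mean") <- m
  out
}
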