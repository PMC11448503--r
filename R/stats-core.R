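#' Statistical primitives
#'
#' Shared, exactly-specified test primitives used by every stage of the
#' pipeline: Spearman correlation with mid-rank ties, Benjamini-Hochberg
#' FDR, the one-tailed (upper) hypergeometric test, the two-sided
#' Mann-Whitney test and the two-sample Kolmogorov-Smirnov test. Each test
#' returns a one-row tibble with columns `statistic`, `p_value`, `method`,
#' `n_x`, `n_y` so results bind into tidy tables.
#'
#' @name stats_core
NULL

test_result <- function(statistic, p_value, method, n_x, n_y = NA_integer_) {
  tibble::tibble(statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 method = method,
                 n_x = as.integer(n_x), n_y = as.integer(n_y))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties); the
#' p-value uses the t approximation
#' `p = 2 P(T_{n-2} >= |rho| sqrt((n-2)/(1-rho^2)))`, clamped to 0 for
#' `|rho| = 1`.
#'
#' @param x,y numeric vectors of equal length >= 3, each with at least two
#'   distinct values.
#' @return One-row test-result tibble with `statistic = rho`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) {
    rlang::abort("x and y must have equal length >= 3.",
                 class = "anchortraj_validation_error")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    rlang::abort("undefined correlation: constant vector.",
                 class = "anchortraj_validation_error")
  }
  rho <- stats::cor(rank(x), rank(y))
  test_result(rho, spearman_p(rho, n), "spearman-t", n, n)
}

# Vectorised t-approximation p for Spearman rho at sample size n.
spearman_p <- function(rho, n) {
  rho <- pmin(1, pmax(-1, rho))
  p <- numeric(length(rho))
  edge <- abs(rho) >= 1 - 1e-14
  p[edge] <- 0
  tt <- abs(rho[!edge]) * sqrt((n - 2) / (1 - rho[!edge]^2))
  p[!edge] <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  pmin(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) m / j`, mapped back to
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) {
    rlang::abort("empty p-value vector.", class = "anchortraj_validation_error")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("p-values must lie in [0, 1].",
                 class = "anchortraj_validation_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' One-tailed (upper) hypergeometric enrichment test
#'
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` from a
#' population of `N` containing `K` successes. Computed in log space via
#' [stats::phyper()]; `p = 1` when `k = 0`.
#'
#' @param k observed successes in the draw.
#' @param K successes in the population.
#' @param n draw size.
#' @param N population size.
#' @return One-row test-result tibble with `statistic = k`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (K > N) rlang::abort("violated: K <= N.", class = "anchortraj_validation_error")
  if (n > N) rlang::abort("violated: n <= N.", class = "anchortraj_validation_error")
  if (k < 0 || k > min(K, n)) {
    rlang::abort("violated: 0 <= k <= min(K, n).",
                 class = "anchortraj_validation_error")
  }
  p <- stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  test_result(k, p, "hypergeometric-upper", n, N)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact permutation p when the pooled sample has no ties and
#' `max(n_x, n_y) <= 10`; otherwise the normal approximation with tie and
#' continuity correction. The branch taken is recorded in `method`.
#'
#' @param x,y numeric samples.
#' @param alternative only `"two.sided"` is used by the pipeline.
#' @return One-row test-result tibble with `statistic = U` of `x`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) {
    rlang::abort("empty sample.", class = "anchortraj_validation_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && max(length(x), length(y)) <= 10
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = use_exact, correct = TRUE))
  test_result(unname(ht$statistic), ht$p.value,
              if (use_exact) "MW-exact" else "MW-normal-tie-corrected",
              length(x), length(y))
}

#' Two-sample Kolmogorov-Smirnov test (asymptotic)
#'
#' `D` is the supremum over pooled points of the ECDF difference; the
#' p-value comes from the asymptotic Kolmogorov distribution at effective
#' size `n m / (n + m)`.
#'
#' @param x,y numeric samples of length >= 2.
#' @return One-row test-result tibble with `statistic = D`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("each sample needs >= 2 values.",
                 class = "anchortraj_validation_error")
  }
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  test_result(unname(ht$statistic), ht$p.value, "KS-asymptotic",
              length(x), length(y))
}
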