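# Independent brute-force oracles used to pin the statistical primitives.
# These deliberately avoid the code paths they check.

# Upper-tail hypergeometric by explicit distribution construction: start at
# the lowest feasible k and walk the pmf with the ratio recurrence, then
# normalise. Accurate to ~1e-14 for N <= 60.
oracle_hyper_pmf <- function(K, n, N) {
  lo <- max(0L, K + n - N)
  hi <- min(K, n)
  pmf <- numeric(hi - lo + 1)
  pmf[1] <- 1
  if (hi > lo) {
    for (x in lo:(hi - 1)) {
      ratio <- (K - x) * (n - x) / ((x + 1) * (N - K - n + x + 1))
      pmf[x - lo + 2] <- pmf[x - lo + 1] * ratio
    }
  }
  list(support = lo:hi, pmf = pmf / sum(pmf))
}

oracle_hyper_upper <- function(k, K, n, N) {
  d <- oracle_hyper_pmf(K, n, N)
  sum(d$pmf[d$support >= k])
}

# Upper-tail probabilities over the whole support in one pass.
oracle_hyper_upper_all <- function(K, n, N) {
  d <- oracle_hyper_pmf(K, n, N)
  rev(cumsum(rev(d$pmf)))
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
oracle_mw_two_sided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  m <- nx * ny / 2
  if (u_obs == m) return(1)
  p <- if (u_obs > m) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(1, 2 * p)
}

# Pearson correlation of mid-ranks, written out from the moment formula.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Hand-rolled BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

# Brute-force GSEA enrichment score: walk the whole ranking and track the
# running sum explicitly.
oracle_gsea_es <- function(stats_sorted, set_genes, weight = 1) {
  genes <- names(stats_sorted)
  hit <- genes %in% set_genes
  w <- abs(stats_sorted)^weight
  tot <- sum(w[hit])
  n_miss <- sum(!hit)
  inc <- ifelse(hit, if (tot > 0) w / tot else 1 / sum(hit), 0) -
    ifelse(hit, 0, 1 / n_miss)
  run <- cumsum(inc)
  i_max <- which.max(run); i_min <- which.min(run)
  max_dev <- max(0, run[i_max]); min_dev <- min(0, run[i_min])
  # same positive-on-tie rule (with tolerance) as the implementation
  if (max_dev >= -min_dev - 1e-12) max_dev else min_dev
}
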