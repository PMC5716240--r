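# Independent oracles, written as direct scalar transcriptions of the defining
# formulas; they share no code with the vectorized implementation paths.

# Variance components transcribed term by term.
oracle_components <- function(p_i, p_j, cov_i, cov_j, n_i, n_j) {
  alpha_i <- 2 * p_i * (1 - p_i)
  alpha_j <- 2 * p_j * (1 - p_j)
  p_bar <- (cov_i * p_i + cov_j * p_j) / (cov_i + cov_j)
  b_s <- (n_i * alpha_i + n_j * alpha_j) / (n_i + n_j - 1)
  num <- 4 * n_i * (p_i - p_bar)^2 + 4 * n_j * (p_j - p_bar)^2 - b_s
  den <- 2 * (2 * n_i * n_j / (n_i + n_j))
  c(a = num / den, b = b_s)
}

# Exact upper-tail hypergeometric probability P(X >= k), X ~ Hyper(N, K, n),
# by summation of the pmf from log binomial coefficients.
oracle_hyper_upper <- function(k, K, N, n) {
  support <- max(0, n - (N - K)):min(K, n)
  pmf <- exp(lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n))
  sum(pmf[support >= k])
}

# One-sided (enrichment) Fisher p for the 2x2 table [a b; c d] by enumerating
# all tables with the observed margins and at least `a` in the top-left cell.
oracle_fisher_greater <- function(a, b, c, d) {
  oracle_hyper_upper(a, a + b, a + b + c + d, a + c)
}
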