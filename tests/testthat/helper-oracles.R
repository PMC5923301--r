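# Independent brute-force oracles used to cross-check the package's
# percentile, correlation and rank-sum routines.

# linear-interpolation percentile from first principles
oracle_quantile <- function(x, p) {
  s <- unname(sort(x))
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# average ranks computed pairwise, without rank()
oracle_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_ranks(x), oracle_ranks(y))
}

# U statistic for the first group, counted pair by pair
oracle_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bi in b) {
    u <- u + (ai > bi) + 0.5 * (ai == bi)
  }
  u
}

# a small random tpm-scale expression matrix (strictly positive)
random_tpm <- function(n_samples, n_transcripts, seed) {
  set.seed(seed)
  vals <- matrix(exp(rnorm(n_samples * n_transcripts, 5, 2)),
                 nrow = n_samples,
                 dimnames = list(paste0("S", seq_len(n_samples)),
                                 paste0("T", seq_len(n_transcripts))))
  vals <- 1e6 * vals / rowSums(vals)
  expression_matrix(vals, scale = "tpm")
}
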