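# Mann-Whitney-Wilcoxon rank-sum comparison of per-individual toxin counts
# between venom types. Implemented directly (rather than wrapping
# stats::wilcox.test) because the analysis needs an exact permutation p-value
# that also works on tied data by explicit request, together with the
# tie-corrected, continuity-corrected normal approximation.

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' The statistic is the Mann-Whitney U for the first group:
#' `W = #\{(a,b): a > b\} + 0.5 * #\{(a,b): a = b\}` over all cross pairs,
#' equivalently the rank sum of the first group minus `n1(n1+1)/2`. With
#' `method = "auto"` the p-value is exact (enumeration of all
#' `choose(n1+n2, n1)` group labelings) when the pooled data has no ties and
#' the enumeration is small, and otherwise uses the normal approximation
#' with tie-corrected variance and continuity correction. Two-sided by
#' default.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @param method `"auto"`, `"exact"` (enumeration; valid with ties as a
#'   permutation test) or `"normal_approx"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param max_enumeration Largest `choose(n1+n2, n1)` that `"auto"` will
#'   enumerate.
#' @return List with `w_statistic`, `p_value`, `method` (the one actually
#'   used), `n1`, `n2` and `df_echo` (`n1 + n2 - 2`; reported for
#'   comparability with published summaries — degrees of freedom play no
#'   role in a rank-sum test).
#' @export
mann_whitney <- function(group_a, group_b,
                         method = c("auto", "exact", "normal_approx"),
                         alternative = c("two.sided", "less", "greater"),
                         max_enumeration = 1e6) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be nonempty")
  }
  n1 <- length(group_a); n2 <- length(group_b)
  w <- .u_statistic(group_a, group_b)
  pooled <- c(group_a, group_b)
  has_ties <- anyDuplicated(pooled) > 0
  if (method == "auto") {
    method <- if (!has_ties && choose(n1 + n2, n1) <= max_enumeration) {
      "exact"
    } else {
      "normal_approx"
    }
  }
  p <- if (method == "exact") {
    .exact_p(pooled, n1, w, alternative)
  } else {
    .normal_p(pooled, n1, n2, w, alternative)
  }
  list(w_statistic = w, p_value = p, method = method,
       n1 = n1, n2 = n2, df_echo = n1 + n2 - 2L)
}

.u_statistic <- function(a, b) {
  cmp <- outer(a, b, ">")
  eq <- outer(a, b, "==")
  sum(cmp) + 0.5 * sum(eq)
}

# Exact p by enumerating every assignment of the pooled values to a group of
# size n1; with ties this is the permutation-test p-value.
.exact_p <- function(pooled, n1, w, alternative) {
  idx <- utils::combn(length(pooled), n1)
  ws <- apply(idx, 2, function(i) .u_statistic(pooled[i], pooled[-i]))
  total <- ncol(idx)
  p_le <- sum(ws <= w) / total
  p_ge <- sum(ws >= w) / total
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less      = p_le,
         greater   = p_ge)
}

# Normal approximation with tie-corrected variance and continuity correction.
.normal_p <- function(pooled, n1, n2, w, alternative) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  sigma <- sqrt(sigma2)
  cc <- switch(alternative,
               two.sided = sign(w - mu) * 0.5,
               greater   = 0.5,
               less      = -0.5)
  z <- (w - mu - cc) / sigma
  switch(alternative,
         two.sided = min(1, 2 * stats::pnorm(-abs(z))),
         less      = stats::pnorm(z),
         greater   = stats::pnorm(z, lower.tail = FALSE))
}
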