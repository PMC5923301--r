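named_clr <- function(x, ids = paste0("T", seq_along(x))) {
  stats::setNames(x - mean(x), ids)
}

test_that("the null threshold is the interpolated percentile of |delta clr|", {
  v <- seq(0, 9.9, by = 0.1)
  ids <- paste0("N", seq_along(v))
  clr_i <- stats::setNames(v, ids)
  clr_j <- stats::setNames(rep(0, length(v)), ids)
  expect_equal(null_threshold(clr_i, clr_j, ids), 9.801)
  expect_equal(null_threshold(clr_i, clr_i, ids), 0)
  expect_equal(null_threshold(clr_j, clr_i, ids),
               null_threshold(clr_i, clr_j, ids))   # symmetric in (i, j)
  expect_error(null_threshold(clr_i, clr_j, ids[1]), "at least 2")
  expect_error(null_threshold(clr_i, clr_j[rev(ids)], ids), "universe")
  # empirical (inverse-ECDF) variant returns an order statistic
  expect_equal(null_threshold(clr_i, clr_j, ids, type = "empirical"),
               sort(v)[ceiling(0.99 * length(v))])
})

test_that("the percentile routine matches a brute-force oracle", {
  set.seed(101)
  for (k in 1:100) {
    n <- sample(5:200, 1)
    ids <- paste0("N", 1:n)
    a <- stats::setNames(rnorm(n), ids)
    b <- stats::setNames(rnorm(n), ids)
    p <- runif(1, 0.5, 0.999)
    expect_equal(null_threshold(a, b, ids, percentile = 100 * p),
                 oracle_quantile(abs(a - b), p), tolerance = 1e-12)
  }
})

test_that("outlier flagging is strict and directional", {
  ids <- c(paste0("N", 1:50), "tox1", "tox2")
  set.seed(5)
  base <- rnorm(52, 0, 0.1)
  clr_i <- stats::setNames(base, ids)
  clr_j <- clr_i
  thr <- null_threshold(clr_i, clr_j + rnorm(52, 0, 0.1), paste0("N", 1:50))
  expect_equal(nrow(flag_outliers(clr_i, clr_i, c("tox1", "tox2"), thr = 1)), 0)

  # a delta exactly at the threshold is not "outside"
  clr_k <- clr_i
  clr_k["tox1"] <- clr_i["tox1"] - 2
  expect_equal(nrow(flag_outliers(clr_i, clr_k, "tox1", threshold = 2)), 0)
  out <- flag_outliers(clr_i, clr_k, "tox1", threshold = 1.999)
  expect_equal(out$transcript_id, "tox1")
  expect_equal(out$direction, "up_in_i")
  expect_equal(out$delta_clr, 2)

  # spiked toxin far beyond the null width is the only flag
  clr_s <- clr_i
  clr_s["tox2"] <- clr_s["tox2"] + 10
  noise_j <- clr_i + rnorm(52, 0, 0.05)
  thr2 <- null_threshold(clr_s, noise_j, paste0("N", 1:50))
  out2 <- flag_outliers(clr_s, noise_j, c("tox1", "tox2"), thr2)
  expect_equal(out2$transcript_id, "tox2")
  expect_equal(out2$direction, "up_in_i")
})

test_that("swapping the pair negates deltas and swaps directions", {
  set.seed(31)
  ids <- c(paste0("N", 1:100), paste0("X", 1:10))
  a <- stats::setNames(rnorm(110), ids)
  b <- stats::setNames(rnorm(110, 0, 3), ids)
  thr <- null_threshold(a, b, paste0("N", 1:100))
  o1 <- flag_outliers(a, b, paste0("X", 1:10), thr)
  o2 <- flag_outliers(b, a, paste0("X", 1:10), thr)
  expect_equal(o1$transcript_id, o2$transcript_id)
  expect_equal(o1$delta_clr, -o2$delta_clr)
  expect_identical(o1$direction == "up_in_i", o2$direction == "up_in_j")
  # enlarging the threshold can only shrink the outlier set
  o3 <- flag_outliers(a, b, paste0("X", 1:10), thr * 1.5)
  expect_true(all(o3$transcript_id %in% o1$transcript_id))
})

test_that("correlations match direct-formula oracles", {
  ids <- paste0("T", 1:50)
  set.seed(12)
  x <- stats::setNames(rnorm(50), ids)
  expect_equal(unname(pair_correlations(x, x, ids)), c(1, 1, 1))
  y <- -x
  expect_equal(unname(pair_correlations(x, y, ids)), c(-1, -1, 1))
  for (k in 1:100) {
    a <- stats::setNames(rnorm(50), ids)
    b <- stats::setNames(rnorm(50) + 0.3 * a, ids)
    if (k %% 3 == 0) b[sample(50, 5)] <- b[1]   # inject ties
    got <- pair_correlations(a, b, ids)
    expect_equal(got[["pearson_r"]], oracle_pearson(a, b), tolerance = 1e-12)
    expect_equal(got[["spearman_rho"]], oracle_spearman(a, b),
                 tolerance = 1e-12)
    expect_equal(got[["r_squared"]], oracle_pearson(a, b)^2, tolerance = 1e-12)
  }
  flat <- stats::setNames(rep(1, 50), ids)
  expect_true(all(is.na(pair_correlations(x, flat, ids))))
  expect_error(pair_correlations(x[1:2], x[1:2], ids[1:2]), "at least 3")
})

test_that("pairwise aggregation saturates for a type-exclusive block", {
  # toxins high in every B individual, delta-level in every A individual
  set.seed(44)
  n_ntx <- 200
  ids <- c(paste0("N", 1:n_ntx), paste0("SVMP-", 1:5), paste0("OTH-", 1:5))
  samples <- c(paste0("A", 1:5), paste0("B", 1:4))
  types <- stats::setNames(rep(c("A", "B"), c(5, 4)), samples)
  tpm <- matrix(exp(rnorm(9 * length(ids), 5, 0.3)), nrow = 9,
                dimnames = list(samples, ids))
  tpm[types == "B", paste0("SVMP-", 1:5)] <-
    tpm[types == "B", paste0("SVMP-", 1:5)] * 50   # abundant where present
  tpm[types == "A", paste0("SVMP-", 1:5)] <- 0
  tpm <- expression_matrix(1e6 * tpm / rowSums(tpm), "tpm")
  clr <- clr_transform(replace_zeros(tpm))
  agg <- aggregate_pairs(clr, types, paste0("N", 1:n_ntx),
                         c(paste0("SVMP-", 1:5), paste0("OTH-", 1:5)))
  svmp <- agg[grepl("^SVMP", agg$transcript_id), ]
  expect_true(all(svmp$UpB == 20))
  expect_true(all(svmp$UpA == 0))
  expect_true(all(svmp$delta == 20))
  expect_true(all(agg$n_pairs == 20))
  expect_true(all(agg$UpB + agg$UpA <= agg$n_pairs))
  pairs <- attr(agg, "pairs")
  expect_equal(nrow(pairs), 20)
  expect_true(all(pairs$threshold > 0))
  expect_true(all(abs(pairs$r2_nontoxin - pairs$pearson_nontoxin^2) < 1e-12))
})

test_that("identical cohorts produce no outliers and average directions work", {
  set.seed(50)
  ids <- c(paste0("N", 1:100), paste0("X", 1:5))
  row <- exp(rnorm(105, 5, 1))
  tpm <- matrix(rep(row, 4), nrow = 4, byrow = TRUE,
                dimnames = list(c("A1", "A2", "B1", "B2"), ids))
  tpm <- expression_matrix(1e6 * tpm / rowSums(tpm), "tpm")
  types <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  clr <- clr_transform(tpm)
  agg <- aggregate_pairs(clr, types, paste0("N", 1:100), paste0("X", 1:5))
  expect_true(all(agg$UpB == 0 & agg$UpA == 0))

  # average pseudo-samples: direction column reflects AveB - AveA
  tpm2 <- unclass(tpm)
  tpm2 <- rbind(tpm2, AveA = colMeans(tpm2[1:2, ]), AveB = colMeans(tpm2[3:4, ]))
  tpm2["AveB", "X1"] <- tpm2["AveB", "X1"] * 2
  tpm2["AveA", "X2"] <- tpm2["AveA", "X2"] * 2
  clr2 <- clr_transform(expression_matrix(tpm2, "tpm"))
  agg2 <- aggregate_pairs(clr2, types, paste0("N", 1:100), paste0("X", 1:5),
                          averages = c("AveA", "AveB"))
  expect_equal(agg2$aveB_vs_aveA[agg2$transcript_id == "X1"], "Up")
  expect_equal(agg2$aveB_vs_aveA[agg2$transcript_id == "X2"], "Down")
})

test_that("the OLS prediction band flags points off the nontoxin line", {
  ids <- c(paste0("N", 1:100), "tox")
  set.seed(61)
  x <- stats::setNames(c(rnorm(100), 0), ids)
  y <- x
  y["tox"] <- 10
  out <- ols_band_outliers(x, y, paste0("N", 1:100), "tox")
  expect_equal(out$transcript_id, "tox")
  expect_equal(out$direction, "up_in_j")
  # toxins on the fitted line are never flagged
  y2 <- x
  expect_equal(nrow(ols_band_outliers(x, y2, paste0("N", 1:100), "tox")), 0)
  flatx <- stats::setNames(c(rep(1, 100), 0), ids)
  expect_error(ols_band_outliers(flatx, y, paste0("N", 1:100), "tox"),
               "degenerate")
})

test_that("held-out null points fall outside the 99% band about 1% of the time", {
  set.seed(71)
  misses <- 0L
  total <- 0L
  for (r in 1:50) {
    n <- 300
    ids <- c(paste0("N", 1:n), paste0("H", 1:100))
    x <- rnorm(n + 100)
    y <- 0.8 * x + rnorm(n + 100, 0, 0.5)
    xc <- stats::setNames(x, ids)
    yc <- stats::setNames(y, ids)
    out <- ols_band_outliers(xc, yc, paste0("N", 1:n), paste0("H", 1:100))
    misses <- misses + nrow(out)
    total <- total + 100L
  }
  expect_gt(misses / total, 0.003)
  expect_lt(misses / total, 0.025)
})

test_that("abs-difference and OLS-band methods agree on direction", {
  set.seed(81)
  for (r in 1:10) {
    ids <- c(paste0("N", 1:200), paste0("X", 1:20))
    a <- stats::setNames(rnorm(220), ids)
    b <- stats::setNames(a + rnorm(220, 0, 0.4), ids)
    b[paste0("X", 1:5)] <- b[paste0("X", 1:5)] + 5
    b[paste0("X", 6:10)] <- b[paste0("X", 6:10)] - 5
    thr <- null_threshold(a, b, paste0("N", 1:200))
    abs_out <- flag_outliers(a, b, paste0("X", 1:20), thr)
    ols_out <- ols_band_outliers(a, b, paste0("N", 1:200), paste0("X", 1:20))
    both <- intersect(abs_out$transcript_id, ols_out$transcript_id)
    for (id in both) {
      # abs-diff reports direction of i vs j; the band reports j's axis
      expect_identical(
        abs_out$direction[abs_out$transcript_id == id] == "up_in_i",
        ols_out$direction[ols_out$transcript_id == id] == "up_in_i")
    }
  }
})
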