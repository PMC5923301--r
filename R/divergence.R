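# Pairwise expression-divergence testing: the null distribution of
# between-individual clr differences is built from the nontoxin
# transcripts, and toxins whose absolute clr difference exceeds its 99th
# percentile are flagged as outliers.

#' Empirical null threshold for one pair of individuals
#'
#' The threshold is the `percentile`-th percentile of the absolute clr
#' differences of the nontoxin transcripts between the two individuals.
#' Nontoxins are presumed not to diverge between venom types, so the spread
#' of their differences measures technical plus neutral biological noise.
#'
#' @param clr_i,clr_j Named clr vectors for the two individuals over the same
#'   transcript universe.
#' @param nontoxin_ids At least two nontoxin transcript ids.
#' @param percentile Percentile of the null (default 99).
#' @param type `"interpolated"` (linear interpolation between order
#'   statistics, the default) or `"empirical"` (inverse ECDF).
#' @return Nonnegative scalar threshold.
#' @export
null_threshold <- function(clr_i, clr_j, nontoxin_ids, percentile = 99,
                           type = c("interpolated", "empirical")) {
  type <- match.arg(type)
  .check_universe(clr_i, clr_j)
  miss <- setdiff(nontoxin_ids, names(clr_i))
  if (length(miss) > 0) stop("nontoxin id not in clr vectors: ", miss[1])
  if (length(nontoxin_ids) < 2) stop("need at least 2 nontoxins for a null")
  d <- abs(clr_i[nontoxin_ids] - clr_j[nontoxin_ids])
  unname(stats::quantile(d, probs = percentile / 100,
                         type = if (type == "interpolated") 7L else 1L))
}

.check_universe <- function(clr_i, clr_j) {
  if (is.null(names(clr_i)) || is.null(names(clr_j)) ||
      !identical(names(clr_i), names(clr_j))) {
    stop("clr vectors must be named over the same transcript universe")
  }
  invisible(TRUE)
}

#' Flag toxin outliers in one pairwise comparison
#'
#' A toxin is an outlier when its absolute clr difference lies strictly
#' outside the null threshold; ties at the threshold are not flagged.
#' Direction is `"up_in_i"` when the toxin is higher in the first individual.
#'
#' @param clr_i,clr_j Named clr vectors.
#' @param toxin_ids Toxin ids to test.
#' @param threshold From [null_threshold()].
#' @return A `data.frame` with `transcript_id`, `delta_clr` (`clr_i - clr_j`)
#'   and `direction`.
#' @export
flag_outliers <- function(clr_i, clr_j, toxin_ids, threshold) {
  .check_universe(clr_i, clr_j)
  miss <- setdiff(toxin_ids, names(clr_i))
  if (length(miss) > 0) stop("toxin id not in clr vectors: ", miss[1])
  delta <- clr_i[toxin_ids] - clr_j[toxin_ids]
  hit <- abs(delta) > threshold
  data.frame(transcript_id = toxin_ids[hit],
             delta_clr = unname(delta[hit]),
             direction = ifelse(delta[hit] > 0, "up_in_i", "up_in_j"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate outlier calls over all A x B pairs
#'
#' Runs [null_threshold()] and [flag_outliers()] for every (Type A, Type B)
#' pair of individuals (`nA * nB` comparisons; 5 x 4 = 20 in the packaged
#' study design) and counts, per toxin, the pairs in which it was up in the
#' B member (`UpB`) and up in the A member (`UpA`). When average
#' pseudo-individuals are present in the matrix, their head-to-head
#' comparison direction is reported as well.
#'
#' @param clr clr-scale [expression_matrix()] (samples x transcripts).
#' @param types Named `"A"`/`"B"` vector for the true individuals; rows of
#'   `clr` not named here (e.g. `"AveA"`, `"AveB"`) are not used for pair
#'   counting.
#' @param nontoxin_ids,toxin_ids Column subsets defining the null and the
#'   tested set.
#' @param percentile Null percentile (default 99).
#' @param averages Optional length-2 character vector `c(aveA, aveB)` of row
#'   names holding the average pseudo-individuals.
#' @return A `data.frame` with one row per toxin: `transcript_id`, `UpB`,
#'   `UpA`, `delta` (= UpB - UpA), `n_pairs`, and `aveB_vs_aveA` direction
#'   (`"Up"`/`"Down"`/`"No Difference"`, `NA` when no averages given), sorted
#'   by decreasing `delta`. Per-pair thresholds and correlations are attached
#'   as attribute `pairs` (a `data.frame`).
#' @export
aggregate_pairs <- function(clr, types, nontoxin_ids, toxin_ids,
                            percentile = 99, averages = NULL) {
  .assert_scale(clr, "clr")
  samples <- intersect(rownames(clr), names(types))
  a_ids <- samples[types[samples] == "A"]
  b_ids <- samples[types[samples] == "B"]
  if (length(a_ids) == 0 || length(b_ids) == 0) {
    stop("need at least one individual of each venom type")
  }
  vals <- unclass(clr)
  up_b <- up_a <- stats::setNames(integer(length(toxin_ids)), toxin_ids)
  pair_rows <- list()
  for (a in a_ids) {
    for (b in b_ids) {
      clr_a <- vals[a, ]; clr_b <- vals[b, ]
      thr <- null_threshold(clr_a, clr_b, nontoxin_ids, percentile)
      out <- flag_outliers(clr_a, clr_b, toxin_ids, thr)
      up_a_ids <- out$transcript_id[out$direction == "up_in_i"]
      up_b_ids <- out$transcript_id[out$direction == "up_in_j"]
      up_a[up_a_ids] <- up_a[up_a_ids] + 1L
      up_b[up_b_ids] <- up_b[up_b_ids] + 1L
      ct <- pair_correlations(clr_a, clr_b, toxin_ids)
      cn <- pair_correlations(clr_a, clr_b, nontoxin_ids)
      pair_rows[[paste(a, b)]] <- data.frame(
        sample_A = a, sample_B = b, threshold = thr,
        n_outliers = nrow(out),
        spearman_toxin = ct[["spearman_rho"]],
        pearson_toxin = ct[["pearson_r"]],
        r2_toxin = ct[["r_squared"]],
        spearman_nontoxin = cn[["spearman_rho"]],
        pearson_nontoxin = cn[["pearson_r"]],
        r2_nontoxin = cn[["r_squared"]],
        stringsAsFactors = FALSE)
    }
  }
  ave_dir <- rep(NA_character_, length(toxin_ids))
  if (!is.null(averages)) {
    stopifnot(length(averages) == 2, all(averages %in% rownames(clr)))
    d <- vals[averages[2], toxin_ids] - vals[averages[1], toxin_ids]
    ave_dir <- ifelse(d > 0, "Up", ifelse(d < 0, "Down", "No Difference"))
  }
  out <- data.frame(transcript_id = toxin_ids,
                    UpB = as.integer(up_b), UpA = as.integer(up_a),
                    delta = as.integer(up_b - up_a),
                    n_pairs = length(a_ids) * length(b_ids),
                    aveB_vs_aveA = ave_dir,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$delta, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pairs") <- do.call(rbind, c(pair_rows, list(make.row.names = FALSE)))
  out
}

#' Correlation statistics for one pairwise comparison
#'
#' Spearman's rank correlation (average ranks on ties), Pearson's
#' correlation, and the coefficient of determination (the squared Pearson
#' correlation of the two clr vectors), over a transcript subset.
#'
#' @param clr_i,clr_j Named clr vectors.
#' @param subset_ids At least three transcript ids.
#' @return Named numeric vector `spearman_rho`, `pearson_r`, `r_squared`
#'   (`NA` when a vector has zero variance: the correlation is undefined).
#' @export
pair_correlations <- function(clr_i, clr_j, subset_ids) {
  .check_universe(clr_i, clr_j)
  if (length(subset_ids) < 3) stop("need at least 3 transcripts")
  x <- clr_i[subset_ids]; y <- clr_j[subset_ids]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(spearman_rho = NA_real_, pearson_r = NA_real_,
             r_squared = NA_real_))
  }
  r <- stats::cor(x, y, method = "pearson")
  c(spearman_rho = stats::cor(x, y, method = "spearman"),
    pearson_r = r, r_squared = r^2)
}

#' OLS prediction-band outlier flagging (variant method)
#'
#' Variant of the divergence test used for scatterplot-style displays: an
#' ordinary least squares line of `clr_j` on `clr_i` is fitted through the
#' nontoxins, and toxins outside the `level` prediction interval around that
#' line are flagged — above the band means up in `j`, below means up in `i`.
#' This is a labeled variant; the absolute-difference percentile rule is the
#' primary method and the one used for pairwise aggregation.
#'
#' @param clr_i,clr_j Named clr vectors.
#' @param nontoxin_ids At least 3 nontoxins to fit through.
#' @param toxin_ids Toxins to test.
#' @param level Prediction-interval level (default 0.99).
#' @return A `data.frame` with `transcript_id`, `residual` and `direction`
#'   (`"up_in_j"` above the band, `"up_in_i"` below).
#' @export
ols_band_outliers <- function(clr_i, clr_j, nontoxin_ids, toxin_ids,
                              level = 0.99) {
  .check_universe(clr_i, clr_j)
  if (length(nontoxin_ids) < 3) stop("need at least 3 nontoxins to fit")
  x <- clr_i[nontoxin_ids]
  if (stats::sd(x) == 0) stop("degenerate fit: clr_i has zero variance")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = clr_j[nontoxin_ids]))
  pred <- stats::predict(fit,
                         newdata = data.frame(x = unname(clr_i[toxin_ids])),
                         interval = "prediction", level = level)
  yt <- clr_j[toxin_ids]
  above <- yt > pred[, "upr"]
  below <- yt < pred[, "lwr"]
  hit <- above | below
  data.frame(transcript_id = toxin_ids[hit],
             residual = unname(yt[hit] - pred[hit, "fit"]),
             direction = ifelse(above[hit], "up_in_j", "up_in_i"),
             stringsAsFactors = FALSE, row.names = NULL)
}
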