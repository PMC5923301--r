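# Zero replacement and the centered log-ratio transform. TPM values are
# compositional (each sample sums to 1e6), so all comparisons work on
# log-ratios; zeros must first be replaced by a small positive amount
# without disturbing the ratios among the observed parts.

#' Multiplicative zero replacement
#'
#' Replaces each zero in a row with a small positive value `delta` and
#' rescales the nonzero parts by `1 - sum(delta)/total` so the row total is
#' preserved. Ratios among the originally nonzero parts are untouched (the
#' multiplicative property). With `delta = "auto"` each row uses
#' 0.65 x its smallest positive value — a conventional choice for
#' continuous compositions, recorded in the output so runs are reproducible.
#'
#' @param expr An [expression_matrix()] on the tpm scale; every row must have
#'   at least one positive entry.
#' @param method `"multiplicative_simple"` (fixed `delta`) or
#'   `"fraction_of_min"` (`delta` is a fraction of the row's smallest
#'   positive value).
#' @param delta `"auto"` (equivalent to `fraction_of_min` with fraction
#'   0.65), or a positive scalar: the replacement value
#'   (`multiplicative_simple`) or the fraction (`fraction_of_min`).
#' @return A strictly positive tpm-scale matrix with attribute
#'   `zero_replacement` (list: method, delta, n_replaced).
#' @export
replace_zeros <- function(expr,
                          method = c("multiplicative_simple", "fraction_of_min"),
                          delta = "auto") {
  method <- match.arg(method)
  .assert_scale(expr, "tpm")
  vals <- unclass(expr)
  if (any(rowSums(vals > 0) == 0)) stop("a row has no positive entries")
  auto <- identical(delta, "auto")
  if (auto) {
    method <- "fraction_of_min"
    delta <- 0.65
  }
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    stop("delta must be 'auto' or a positive scalar")
  }
  n_replaced <- 0L
  for (i in seq_len(nrow(vals))) {
    row <- vals[i, ]
    zero <- row == 0
    if (!any(zero)) next
    minpos <- min(row[!zero])
    d <- if (method == "fraction_of_min") delta * minpos else delta
    if (d >= minpos) {
      stop("replacement delta (", format(d),
           ") must be smaller than the smallest positive value (",
           format(minpos), ") in row ", rownames(vals)[i])
    }
    total <- sum(row)
    shrink <- 1 - sum(zero) * d / total
    row[!zero] <- row[!zero] * shrink
    row[zero] <- d
    vals[i, ] <- row
    n_replaced <- n_replaced + sum(zero)
  }
  out <- expression_matrix(vals, scale = "tpm")
  attr(out, "zero_replacement") <- list(method = method, delta = delta,
                                        auto = auto, n_replaced = n_replaced)
  out
}

#' Centered log-ratio transform
#'
#' Per sample (row), `clr_i = ln(x_i) - mean_j ln(x_j)`, with the mean taken
#' over `subset` (default: every transcript supplied — toxins and nontoxins
#' together when both are present). The transform linearizes the composition
#' while preserving the rank order within a row, and is invariant to
#' rescaling a row by a positive constant.
#'
#' @param expr Strictly positive [expression_matrix()] (tpm or proportion);
#'   run [replace_zeros()] first if there are zeros.
#' @param subset Transcript ids over which the geometric mean is taken and
#'   which are returned (default all columns).
#' @return An [expression_matrix()] on the clr scale (rows sum to 0), with
#'   attribute `clr_subset_n` recording the subset size.
#' @export
clr_transform <- function(expr, subset = NULL) {
  if (expr_scale(expr) == "clr") stop("input is already clr-transformed")
  if (is.null(subset)) subset <- colnames(expr)
  miss <- setdiff(subset, colnames(expr))
  if (length(miss) > 0) stop("subset id not in matrix: ", miss[1])
  vals <- unclass(expr)[, subset, drop = FALSE]
  if (any(vals <= 0)) {
    stop("clr needs strictly positive values; run replace_zeros() first")
  }
  lv <- log(vals)
  out <- expression_matrix(lv - rowMeans(lv), scale = "clr")
  attr(out, "clr_subset_n") <- length(subset)
  out
}

#' Append a venom-type average pseudo-individual
#'
#' Averages the TPM values of all samples of one venom type, transcript by
#' transcript, and appends the result as a new row (e.g. "AveA"). Averaging
#' happens on the TPM scale, before zero replacement and clr — the pipeline
#' order is average, then replace zeros, then transform.
#'
#' @param expr tpm-scale [expression_matrix()].
#' @param types Named venom-type vector covering the rows of `expr`.
#' @param which `"A"` or `"B"`.
#' @param name Row name for the pseudo-sample (default `"AveA"`/`"AveB"`).
#' @return `expr` with the average row appended.
#' @export
average_type_individual <- function(expr, types, which = c("A", "B"),
                                    name = NULL) {
  which <- match.arg(which)
  .assert_scale(expr, "tpm")
  members <- rownames(expr)[types[rownames(expr)] == which]
  members <- members[!is.na(members)]
  if (length(members) == 0) stop("no samples of type ", which)
  if (is.null(name)) name <- paste0("Ave", which)
  avg <- colMeans(unclass(expr)[members, , drop = FALSE])
  vals <- rbind(unclass(expr), avg)
  rownames(vals) <- c(rownames(expr), name)
  expression_matrix(vals, scale = "tpm")
}
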