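# Expression matrices are stored samples x transcripts with a `scale`
# attribute ("tpm", "proportion" or "clr"); clr rows must sum to ~0, tpm
# entries must be nonnegative.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, samples in rows, transcripts in columns,
#'   with both dimnames set.
#' @param scale One of `"tpm"`, `"proportion"`, `"clr"`.
#' @return The matrix with class `expr_matrix` and the `scale` attribute set.
#' @export
expression_matrix <- function(values, scale = c("tpm", "proportion", "clr")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("values needs sample rownames and transcript colnames")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate sample or transcript ids")
  }
  if (scale %in% c("tpm", "proportion") && any(values < 0)) {
    stop("negative entries are not allowed on the ", scale, " scale")
  }
  if (scale == "clr" && ncol(values) > 0 &&
      any(abs(rowSums(values)) > 1e-8 * ncol(values))) {
    stop("clr rows must sum to 0")
  }
  structure(values, class = c("expr_matrix", class(values)), scale = scale)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d transcripts, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

#' Scale of an expression matrix
#' @param x An `expr_matrix`.
#' @return `"tpm"`, `"proportion"` or `"clr"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale", exact = TRUE)
  if (is.null(s)) stop("not an expression matrix (no scale attribute)")
  s
}

# subsetting keeps class and scale whenever the result is still a matrix;
# drop behaves as for base matrices
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    structure(out, class = class(x), scale = attr(x, "scale"))
  } else {
    out
  }
}

.assert_scale <- function(x, scale) {
  if (!identical(expr_scale(x), scale)) {
    stop("expected an expression matrix on the '", scale, "' scale, got '",
         expr_scale(x), "'")
  }
  invisible(x)
}
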