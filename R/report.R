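# Deterministic TSV/YAML report writer: the same inputs always produce
# byte-identical files.

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a pipeline report directory
#'
#' Writes whichever stage outputs are present in `results` as deterministic
#' TSV files — presence matrix (+/-), per-sample toxin counts, family
#' composition and diversity, the pairwise outlier aggregate (columns UpB,
#' UpA, delta), per-pair correlation statistics, the rank-sum result — plus
#' `params.yaml` echoing the run parameters so a run can be reproduced
#' bit-for-bit.
#'
#' @param results Named list; recognized components: `presence`,
#'   `toxin_counts`, `family_composition`, `family_diversity`,
#'   `outlier_aggregate` (with attribute `pairs`), `ranksum`, `params`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  written <- character()
  emit <- function(df, file) {
    path <- file.path(dir, file)
    .write_tsv(df, path)
    written <<- c(written, path)
  }
  if (!is.null(results$presence)) {
    write_presence_table(results$presence, file.path(dir, "presence_matrix.tsv"))
    written <- c(written, file.path(dir, "presence_matrix.tsv"))
  }
  if (!is.null(results$toxin_counts)) {
    emit(data.frame(sample_id = names(results$toxin_counts),
                    toxins_present = as.integer(results$toxin_counts)),
         "toxin_counts.tsv")
  }
  if (!is.null(results$family_composition)) {
    emit(results$family_composition, "family_composition.tsv")
  }
  if (!is.null(results$family_diversity)) {
    emit(results$family_diversity, "family_diversity.tsv")
  }
  agg <- results$outlier_aggregate
  if (!is.null(agg)) {
    emit(data.frame(toxin_id = agg$transcript_id, UpB = agg$UpB,
                    UpA = agg$UpA, delta = agg$delta,
                    aveB_vs_aveA = agg$aveB_vs_aveA),
         "outlier_table.tsv")
    pairs <- attr(agg, "pairs")
    if (!is.null(pairs)) emit(pairs, "correlations.tsv")
  } else if (isTRUE(results$empty_outliers)) {
    emit(data.frame(toxin_id = character(), UpB = integer(), UpA = integer(),
                    delta = integer(), aveB_vs_aveA = character()),
         "outlier_table.tsv")
  }
  if (!is.null(results$ranksum)) {
    rs <- results$ranksum
    emit(data.frame(w_statistic = rs$w_statistic, p_value = rs$p_value,
                    method = rs$method, n1 = rs$n1, n2 = rs$n2,
                    df_echo = rs$df_echo),
         "ranksum.tsv")
  }
  params <- results$params
  if (is.null(params)) params <- list()
  yaml::write_yaml(params, file.path(dir, "params.yaml"))
  written <- c(written, file.path(dir, "params.yaml"))
  invisible(written)
}
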