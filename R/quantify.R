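# Abundance normalization, coverage-based presence calling and family
# summaries.

#' Transcripts-per-million from expected counts
#'
#' `tpm_t = 1e6 * (c_t / l_t) / sum_u(c_u / l_u)`. Lengths may be raw or
#' effective lengths; the formula is the same.
#'
#' @param expected_counts Nonnegative numeric vector of per-transcript counts.
#' @param effective_lengths Positive lengths, same length as the counts.
#' @return TPM vector summing to 1e6.
#' @export
compute_tpm <- function(expected_counts, effective_lengths) {
  if (length(expected_counts) != length(effective_lengths)) {
    stop("counts and lengths must have the same length")
  }
  if (any(expected_counts < 0)) stop("counts must be nonnegative")
  if (any(effective_lengths <= 0)) stop("lengths must be positive")
  rate <- expected_counts / effective_lengths
  tot <- sum(rate)
  if (tot == 0) stop("all counts are zero: composition undefined")
  1e6 * rate / tot
}

#' Call transcript presence from a per-base depth vector
#'
#' A transcript counts as present in a sample when at least
#' `min_covered_fraction` of its positions have read depth of at least
#' `min_depth` (default: 5x over 90%). Equivalently, it is absent when more
#' than 10% of the sequence has less than 5x coverage. Presence is
#' independent of the TPM value: mapping artifacts can give a transcript
#' nonzero abundance even when it is not in the transcriptome.
#'
#' @param depth Integer vector of per-base read depths (length = transcript
#'   length).
#' @param min_depth Minimum per-base depth (default 5).
#' @param min_covered_fraction Minimum fraction of positions at that depth
#'   (default 0.90; exactly 90% covered is present).
#' @return `TRUE` if present.
#' @export
call_presence <- function(depth, min_depth = 5, min_covered_fraction = 0.90) {
  if (length(depth) == 0) stop("empty depth vector")
  if (any(depth < 0)) stop("depths must be nonnegative")
  mean(depth >= min_depth) >= min_covered_fraction
}

#' Presence matrix for a reference transcript set
#'
#' Applies [call_presence()] to each (transcript, sample) depth vector of a
#' coverage collection, restricted to `reference_ids` — e.g. profiling a
#' panel of phospholipase A2 loci across individuals.
#'
#' @param coverage Nested list: `coverage[[sample_id]][[transcript_id]]` is a
#'   depth vector.
#' @param reference_ids Transcript ids to profile.
#' @param min_depth,min_covered_fraction Passed to [call_presence()].
#' @return Logical matrix, `reference_ids` x samples.
#' @export
profile_reference_set <- function(coverage, reference_ids,
                                  min_depth = 5, min_covered_fraction = 0.90) {
  samples <- names(coverage)
  out <- matrix(NA, nrow = length(reference_ids), ncol = length(samples),
                dimnames = list(reference_ids, samples))
  for (s in samples) {
    miss <- setdiff(reference_ids, names(coverage[[s]]))
    if (length(miss) > 0) {
      stop("no coverage for ", miss[1], " in sample ", s)
    }
    out[, s] <- vapply(coverage[[s]][reference_ids], call_presence,
                       logical(1), min_depth = min_depth,
                       min_covered_fraction = min_covered_fraction)
  }
  out
}

#' Per-sample toxin counts from a presence matrix
#'
#' @param presence Logical matrix, transcripts x samples.
#' @param toxin_ids Ids to count (must be rows of `presence`).
#' @return Named integer vector of per-sample counts.
#' @export
count_toxins_present <- function(presence, toxin_ids = rownames(presence)) {
  miss <- setdiff(toxin_ids, rownames(presence))
  if (length(miss) > 0) stop("ids missing from presence matrix: ", miss[1])
  colSums(presence[toxin_ids, , drop = FALSE])
}

#' Classify presence patterns by venom type
#'
#' Partitions the transcripts present in at least one sample into:
#' `exclusive_A` (present in one or more Type A individuals, never in B),
#' `exclusive_B` (the converse), `in_all` (present in every individual) and
#' `shared_not_all` (present in both types but not in all individuals).
#'
#' @param presence Logical matrix, transcripts x samples.
#' @param types Named vector of `"A"`/`"B"` labels covering every sample.
#' @return List of four character vectors of transcript ids.
#' @export
classify_presence_patterns <- function(presence, types) {
  samples <- colnames(presence)
  unlabeled <- setdiff(samples, names(types))
  if (length(unlabeled) > 0) stop("unlabeled sample: ", unlabeled[1])
  types <- types[samples]
  if (!all(types %in% c("A", "B"))) stop("venom types must be 'A' or 'B'")
  nA <- rowSums(presence[, types == "A", drop = FALSE])
  nB <- rowSums(presence[, types == "B", drop = FALSE])
  ids <- rownames(presence)
  anywhere <- nA + nB > 0
  in_all <- nA + nB == ncol(presence)
  # in_all takes precedence so the four sets partition even when one venom
  # type has no samples; with both types present the sets are disjoint anyway
  list(
    exclusive_A    = ids[nA > 0 & nB == 0 & !in_all],
    exclusive_B    = ids[nB > 0 & nA == 0 & !in_all],
    in_all         = ids[in_all],
    shared_not_all = ids[anywhere & !in_all & nA > 0 & nB > 0]
  )
}

#' Toxin-family composition per sample
#'
#' Sums TPM by toxin family within each sample and expresses it as a
#' percentage under two denominators: the whole transcriptome (1e6, the TPM
#' total over toxins and nontoxins together) and the sample's toxin TPM sum
#' only (pie-chart-style proportions).
#'
#' @param expr An [expression_matrix()] on the tpm scale.
#' @param catalog Catalog covering every toxin column of `expr`.
#' @return A `data.frame` with columns `sample_id`, `family`, `tpm_sum`,
#'   `percent_total`, `percent_toxin`, `n_transcripts_in_family`.
#' @export
family_composition <- function(expr, catalog) {
  .assert_scale(expr, "tpm")
  tox <- catalog[catalog$class == "toxin", , drop = FALSE]
  ids <- intersect(colnames(expr), tox$transcript_id)
  unknown <- setdiff(colnames(expr),
                     catalog$transcript_id[catalog$class == "nontoxin"])
  unknown <- setdiff(unknown, tox$transcript_id)
  if (length(unknown) > 0) {
    stop("transcript without catalog family: ", unknown[1])
  }
  fam <- stats::setNames(tox$family, tox$transcript_id)[ids]
  sub <- unclass(expr)[, ids, drop = FALSE]
  toxin_total <- rowSums(sub)
  fams <- sort(unique(fam))
  out <- do.call(rbind, lapply(rownames(expr), function(s) {
    sums <- vapply(fams, function(f) sum(sub[s, fam == f]), numeric(1))
    data.frame(sample_id = s, family = fams, tpm_sum = sums,
               percent_total = 100 * sums / 1e6,
               percent_toxin = if (toxin_total[s] > 0)
                 100 * sums / toxin_total[s] else NA_real_,
               n_transcripts_in_family =
                 as.integer(table(fam)[fams]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
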