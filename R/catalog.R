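# Transcript catalog: the universe of transcripts with class/family/length
# annotations.

# PLA2 nomenclature follows the genomic locus names rather than the
# family-rank convention used elsewhere, so the prefix rule cannot see them.
.pla2_ids <- c("Pla2gA1", "Pla2gB1", "Pla2gK",
               "Pla2gA2-MTXA", "Pla2gB2-MTXB", "PLA2-6")

#' Infer toxin family labels from transcript identifiers
#'
#' Toxin transcripts are conventionally named `<FAMILY>-<rank>`, with the rank
#' assigned by decreasing average expression (e.g. `"SVMPIII-4"` is the fourth
#' metalloproteinase of subclass III). The family is the prefix before the
#' final `-<number>`. Phospholipase A2 transcripts carry locus-style names
#' (`Pla2gA1`, `Pla2gB2-MTXB`, ...) and are mapped to family `"PLA2"` by an
#' explicit override. SVMPII and SVMPIII are distinct families.
#'
#' @param ids Character vector of transcript identifiers.
#' @return Character vector of family labels, same length as `ids`.
#' @examples
#' infer_family(c("CTL-12", "SVMPIII-4", "Pla2gA2-MTXA"))
#' @export
infer_family <- function(ids) {
  stopifnot(is.character(ids))
  fam <- sub("-[0-9]+$", "", ids)
  fam[ids %in% .pla2_ids] <- "PLA2"
  fam
}

#' Construct a transcript catalog
#'
#' @param transcript_id Character vector of unique transcript ids.
#' @param class `"toxin"` or `"nontoxin"`, recycled if length 1.
#' @param family Family label per transcript; inferred from the id via
#'   [infer_family()] for toxins when `NULL`. Nontoxins get `""`.
#' @param length_nt Transcript length in nucleotides (`NA` when unknown;
#'   required only by coverage-based operations).
#' @return A `data.frame` with columns `transcript_id`, `class`, `family`,
#'   `length_nt`.
#' @export
transcript_catalog <- function(transcript_id, class = "toxin",
                               family = NULL, length_nt = NA_integer_) {
  transcript_id <- as.character(transcript_id)
  if (anyDuplicated(transcript_id)) {
    stop("duplicate transcript ids: ",
         paste(unique(transcript_id[duplicated(transcript_id)]), collapse = ", "))
  }
  class <- rep_len(as.character(class), length(transcript_id))
  if (!all(class %in% c("toxin", "nontoxin"))) {
    stop("class must be 'toxin' or 'nontoxin'")
  }
  if (is.null(family)) {
    family <- ifelse(class == "toxin", infer_family(transcript_id), "")
  }
  family <- rep_len(as.character(family), length(transcript_id))
  if (any(class == "toxin" & !nzchar(family))) {
    stop("every toxin needs a non-empty family label")
  }
  length_nt <- rep_len(length_nt, length(transcript_id))
  if (any(!is.na(length_nt) & length_nt < 1)) {
    stop("length_nt must be >= 1")
  }
  data.frame(transcript_id = transcript_id, class = class,
             family = family, length_nt = as.integer(length_nt),
             stringsAsFactors = FALSE)
}

#' Per-family transcript counts
#'
#' Counts how many distinct transcripts each toxin family contributes to the
#' catalog — the family "diversity" of the transcriptome.
#'
#' @param catalog A catalog from [transcript_catalog()].
#' @return A `data.frame` with columns `family` and `n_transcripts`, sorted by
#'   decreasing count then family name, with attribute `n_families`.
#' @export
family_diversity <- function(catalog) {
  tox <- catalog[catalog$class == "toxin", , drop = FALSE]
  if (nrow(tox) == 0L) {
    out <- data.frame(family = character(), n_transcripts = integer())
    attr(out, "n_families") <- 0L
    return(out)
  }
  tab <- table(tox$family)
  out <- data.frame(family = names(tab), n_transcripts = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_transcripts, out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_families") <- nrow(out)
  out
}
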