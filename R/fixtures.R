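# Packaged study tables: nine Mojave rattlesnake (Crotalus scutulatus)
# venom-gland transcriptomes, five Type A and four Type B individuals.
# Shipped as plain TSV under inst/extdata with the values exactly as
# printed (including comma thousands separators).

#' Path to a packaged study table
#'
#' @param name One of `"table1_samples"`, `"table2_tpm"`, `"table3_presence"`,
#'   `"table5_pla2"` (the `.tsv` extension is added).
#' @return Absolute path to the installed fixture.
#' @export
venom_fixture <- function(name = c("table1_samples", "table2_tpm",
                                   "table3_presence", "table5_pla2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "venomcomp",
                      mustWork = TRUE)
  path
}

#' Sample metadata for the nine sequenced individuals
#'
#' @return A `data.frame` with one row per individual: `sample_id`,
#'   `venom_type` (A/B), `sex`, `svl_mm`, `mass_g`, `platform`, `read_pairs`,
#'   `merged_reads`.
#' @export
scutulatus_samples <- function() {
  raw <- utils::read.table(venom_fixture("table1_samples"), sep = "\t",
                           header = TRUE, colClasses = "character",
                           stringsAsFactors = FALSE)
  out <- data.frame(
    sample_id    = raw$specimen,
    venom_type   = raw$venom_type,
    sex          = raw$sex,
    svl_mm       = as.numeric(raw$svl_mm),
    mass_g       = as.numeric(raw$mass_g),
    platform     = raw$platform,
    read_pairs   = as.numeric(gsub(",", "", raw$read_pairs)),
    merged_reads = as.numeric(gsub(",", "", raw$merged_reads)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$merged_reads <= 2 * out$read_pairs))
  out
}

#' Toxin TPM expression and catalog for the nine individuals
#'
#' The 75 identified toxin transcripts with their TPM abundances per
#' individual, plus a catalog with inferred family labels (17 families).
#'
#' @return A list with `expression` (9 x 75 [expression_matrix()], tpm) and
#'   `catalog`.
#' @export
scutulatus_toxins <- function() {
  read_expression_table(venom_fixture("table2_tpm"))
}

#' Toxin presence/absence matrix for the nine individuals
#'
#' Built from the printed table of toxins with variable presence plus the 33
#' toxins found in every individual (omitted from that table by convention).
#' Presence was called from read mapping: at least 5x coverage over 90% of
#' the transcript.
#'
#' @return A 75 x 9 logical matrix (transcripts x samples), rows ordered as
#'   in the expression table.
#' @export
scutulatus_presence <- function() {
  cat75 <- scutulatus_toxins()$catalog
  sep <- "\t"
  table_ids <- utils::read.table(venom_fixture("table3_presence"), sep = sep,
                                 header = TRUE, colClasses = "character")[[1]]
  all_present <- setdiff(cat75$transcript_id, table_ids)
  pres <- read_presence_table(venom_fixture("table3_presence"), all_present)
  pres[cat75$transcript_id, , drop = FALSE]
}

#' PLA2 reference-set presence profile
#'
#' Presence (and TPM where present) of the six phospholipase A2 transcripts
#' across the nine sequenced individuals, plus a presence-only panel of four
#' reference specimens from published genome fragments.
#'
#' @return A list with `tpm` (9 x 6 numeric matrix, `NA` = absent),
#'   `presence` (9 x 6 logical), `types` (named venom-type vector) and
#'   `reference` (the 4-specimen presence panel, logical).
#' @export
scutulatus_pla2 <- function() {
  raw <- utils::read.table(venom_fixture("table5_pla2"), sep = "\t",
                           header = TRUE, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  is_clp <- grepl("^CLP", raw$specimen)
  pla2_ids <- colnames(raw)[-(1:2)]
  body <- as.matrix(raw[is_clp, -(1:2), drop = FALSE])
  # a trailing '*' marks the divergent allele; it does not affect the value
  vals <- suppressWarnings(as.numeric(gsub("[,*]", "", body)))
  tpm <- matrix(vals, nrow = sum(is_clp),
                dimnames = list(raw$specimen[is_clp], pla2_ids))
  ref <- as.matrix(raw[!is_clp, -(1:2), drop = FALSE]) == "+"
  rownames(ref) <- raw$specimen[!is_clp]
  types <- stats::setNames(raw$venom_type[is_clp], raw$specimen[is_clp])
  list(tpm = tpm, presence = !is.na(tpm), types = types, reference = ref)
}

#' Reported per-individual toxin counts
#'
#' The study's printed per-individual "toxins present" summary row. Note it
#' disagrees with the packaged presence matrix for one individual: the
#' CLP1835 column of the matrix sums to 64 while the printed row says 66.
#' [count_toxins_present()] on [scutulatus_presence()] yields the matrix
#' sums; this accessor returns the printed row, which is the input of the
#' study's rank-sum comparison.
#'
#' @return Named integer vector of per-individual toxin counts.
#' @export
scutulatus_reported_counts <- function() {
  lines <- readLines(venom_fixture("table3_presence"))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  row <- grep("^#Toxins Present", lines, value = TRUE)
  stopifnot(length(row) == 1)
  vals <- as.integer(strsplit(row, "\t", fixed = TRUE)[[1]][-1])
  stats::setNames(vals, header)
}

#' Venom-type labels for the nine individuals
#' @return Named character vector (`"A"`/`"B"`) keyed by sample id.
#' @export
scutulatus_types <- function() {
  s <- scutulatus_samples()
  stats::setNames(s$venom_type, s$sample_id)
}
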