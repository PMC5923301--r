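# Readers/writers for the tabular formats the pipeline touches: TPM
# expression tables (possibly with comma thousands separators, as printed
# in venom-gland studies), +/- presence tables, and per-base depth tables.

# Parse printed abundance values: comma thousands separators and scientific
# notation are accepted; anything else is an error naming the offending cell.
.parse_number <- function(x, what) {
  out <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  bad <- is.na(out) | !nzchar(trimws(x))
  if (any(bad)) {
    stop("cannot parse value '", x[which(bad)[1]], "' at ", what[which(bad)[1]])
  }
  out
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.read_cells <- function(path, sep) {
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            comment.char = "#")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    stop("ragged table: rows have ", paste(unique(nf), collapse = "/"),
         " fields in ", path)
  }
  utils::read.table(path, sep = sep, quote = "\"", header = FALSE,
                    colClasses = "character", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a TPM expression table
#'
#' Reads a tab- or comma-separated table of transcript abundances with
#' transcript ids in the first column and sample ids in the header row (or
#' transposed, per `orientation`). Printed-style numbers with comma thousands
#' separators (`"274,390.23"`) and scientific notation are accepted. Toxin
#' families are inferred from the transcript ids (see [infer_family()]).
#'
#' @param path Path to the table.
#' @param orientation `"transcripts_in_rows"` (default) or `"samples_in_rows"`.
#' @param class Transcript class recorded in the catalog (`"toxin"` default).
#' @return A list with `expression` (an [expression_matrix()] on the tpm
#'   scale, samples x transcripts) and `catalog` (a [transcript_catalog()]).
#' @export
read_expression_table <- function(path,
                                  orientation = c("transcripts_in_rows",
                                                  "samples_in_rows"),
                                  class = "toxin") {
  orientation <- match.arg(orientation)
  sep <- .detect_sep(path)
  raw <- .read_cells(path, sep)
  header <- as.character(raw[1, -1])
  ids <- as.character(raw[-1, 1])
  body <- raw[-1, -1, drop = FALSE]
  if (orientation == "samples_in_rows") {
    # header holds transcript ids, first column holds sample ids
    tmp <- t(as.matrix(body))
    body <- as.data.frame(tmp, stringsAsFactors = FALSE)
    tr_ids <- header
    header <- ids
    ids <- tr_ids
  }
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id: ", ids[duplicated(ids)][1])
  }
  if (anyDuplicated(header)) stop("duplicate sample id in header")
  vals <- matrix(0, nrow = length(ids), ncol = length(header),
                 dimnames = list(ids, header))
  if (length(ids) > 0) {
    cellnames <- outer(ids, header, function(i, j) paste0("(", i, ", ", j, ")"))
    vals[] <- .parse_number(unlist(body, use.names = FALSE), as.vector(cellnames))
    neg <- which(vals < 0, arr.ind = TRUE)
    if (nrow(neg) > 0) {
      stop("negative value at (", ids[neg[1, 1]], ", ", header[neg[1, 2]], ")")
    }
  }
  tvals <- t(vals)
  dimnames(tvals) <- list(header, ids)   # t() drops zero-extent dimnames
  expr <- expression_matrix(tvals, scale = "tpm")
  list(expression = expr,
       catalog = transcript_catalog(ids, class = class))
}

#' Write an expression matrix as TSV
#'
#' Transcripts in rows, samples in columns, full double precision (so a
#' write/read round trip reproduces the values).
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  vals <- t(unclass(expr))
  out <- data.frame(toxin = rownames(vals),
                    apply(vals, 2, function(col) sprintf("%.17g", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("toxin", colnames(vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a +/- presence table
#'
#' Reads a presence/absence table covering the transcripts whose status
#' varies among individuals. By the printing convention of such tables,
#' transcripts present in every individual are omitted; list them in
#' `all_present_ids` to obtain the full matrix.
#'
#' @param path Path to the +/- table (first column transcript ids, header
#'   sample ids).
#' @param all_present_ids Ids of transcripts omitted from the table because
#'   they are present in all individuals (may be empty).
#' @return A logical matrix, transcripts x samples, rows = table ids followed
#'   by `all_present_ids`.
#' @export
read_presence_table <- function(path, all_present_ids = character()) {
  sep <- .detect_sep(path)
  raw <- .read_cells(path, sep)
  header <- as.character(raw[1, -1])
  ids <- as.character(raw[-1, 1])
  if (anyDuplicated(ids)) stop("duplicate transcript id in presence table")
  overlap <- intersect(ids, all_present_ids)
  if (length(overlap) > 0) {
    stop("ids listed both in the table and in all_present_ids: ",
         paste(overlap, collapse = ", "))
  }
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  body <- trimws(body)
  body[body == "−"] <- "-"   # unicode minus as printed in some tables
  bad <- !(body %in% c("+", "-"))
  if (any(bad)) {
    stop("presence symbol must be '+' or '-', got '", body[which(bad)[1]], "'")
  }
  pres <- body == "+"
  full <- rbind(pres,
                matrix(TRUE, nrow = length(all_present_ids), ncol = length(header)))
  dimnames(full) <- list(c(ids, all_present_ids), header)
  full
}

#' Write a presence matrix as a +/- TSV
#' @param presence Logical matrix, transcripts x samples.
#' @param path Output path.
#' @export
write_presence_table <- function(presence, path) {
  sym <- ifelse(presence, "+", "-")
  out <- data.frame(toxin = rownames(presence), sym,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("toxin", colnames(presence))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-base depth table
#'
#' Accepts the textual form of `samtools depth`-style output: three columns
#' (transcript_id, position, depth), 1-based positions, every position
#' listed. Returns one depth vector per (transcript, file).
#'
#' @param path Path to the 3-column table (with or without a header line).
#' @return Named list of integer depth vectors, one per transcript.
#' @export
read_depth_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) != 3L) stop("depth table must have 3 columns")
  # tolerate a header line
  if (suppressWarnings(is.na(as.integer(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  ids <- raw[[1]]
  pos <- as.integer(raw[[2]])
  depth <- as.integer(raw[[3]])
  if (any(is.na(pos)) || any(is.na(depth)) || any(depth < 0)) {
    stop("positions and depths must be nonnegative integers")
  }
  out <- lapply(split(seq_along(ids), ids), function(idx) {
    p <- pos[idx]
    d <- depth[idx][order(p)]
    p <- sort(p)
    if (!identical(p, seq_len(length(p)))) {
      stop("every position 1..L must be listed exactly once for transcript ",
           ids[idx[1]])
    }
    d
  })
  out[unique(ids)]
}
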