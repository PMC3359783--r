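# Sequence records, FASTA / aligned-FASTA input and output.
#
# A sequence collection is a data.frame with columns `id`, `description`,
# `residues` and class "seq_records".  Residues are uppercase strings over
# the 20 standard amino acids plus X; coordinates in all reports are 1-based
# inclusive, as are internal spans.

#' Construct a sequence record collection
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of amino-acid strings (uppercased).
#' @param description optional free-text descriptions (default "").
#' @param map_nonstandard if `TRUE` (default), the ambiguity/stop codes
#'   B, Z, U, J, O and `*` are mapped to `X` with a warning; if `FALSE`
#'   they are rejected.
#' @return a data.frame of class `seq_records` with columns
#'   `id`, `description`, `residues`.
#' @examples
#' seq_records(c("a", "b"), c("MKLV", "GDSG"))
#' @export
seq_records <- function(id, residues, description = "",
                        map_nonstandard = TRUE) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) == 0L) stop("empty input: no sequence records")
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(residues))) {
    stop("empty residue string for id: ",
         paste(id[!nzchar(residues)], collapse = ", "))
  }
  residues <- sanitize_residues(residues, map_nonstandard)
  out <- data.frame(id = id,
                    description = rep_len(as.character(description),
                                          length(id)),
                    residues = residues,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

# map non-standard codes to X (warning) and reject anything else
sanitize_residues <- function(residues, map_nonstandard = TRUE,
                              allow_gap = FALSE) {
  alphabet <- c(AA_STANDARD, "X", if (allow_gap) "-")
  chars <- strsplit(residues, "", fixed = TRUE)
  bad <- unique(unlist(lapply(chars, function(x) setdiff(x, alphabet))))
  nonstd <- intersect(bad, AA_NONSTANDARD)
  if (length(nonstd)) {
    if (!map_nonstandard) {
      stop("non-standard residues present (set map_nonstandard = TRUE ",
           "to map them to X): ", paste(nonstd, collapse = ", "))
    }
    warning("non-standard residues mapped to X: ",
            paste(nonstd, collapse = ", "))
    residues <- chartr(paste(AA_NONSTANDARD, collapse = ""),
                       strrep("X", length(AA_NONSTANDARD)), residues)
    bad <- setdiff(bad, AA_NONSTANDARD)
  }
  if (length(bad)) {
    stop("residues contain characters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "))
  }
  residues
}

#' Read a protein FASTA file
#'
#' One record per `>` header; wrapped sequence lines are concatenated and
#' input order is preserved.  The id is the first whitespace-delimited token
#' of the header, the remainder becomes the description.
#'
#' @param path path to a FASTA file.
#' @inheritParams seq_records
#' @return a `seq_records` data.frame.
#' @export
read_fasta <- function(path, map_nonstandard = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty input: no FASTA records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seq_records(id, as.character(set), desc,
              map_nonstandard = map_nonstandard)
}

#' Write sequence records as FASTA
#'
#' @param records a `seq_records` data.frame.
#' @param path output path.
#' @param wrap_width residues per sequence line (default 60).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, wrap_width = 60) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty input: no records to write")
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = wrap_width)
  invisible(path)
}

#' Construct an alignment from gapped sequences
#'
#' @param records gapped residue strings (`-` as the gap character), all
#'   of equal padded length: either a plain character vector or a
#'   data.frame with `id`/`residues` columns.
#' @param ids identifiers when `records` is a character vector (default
#'   `seq1`, `seq2`, ...).
#' @return a list of class `aa_alignment` with elements `records` and
#'   `column_count`.
#' @export
alignment <- function(records, ids = NULL) {
  if (is.character(records)) {
    ids <- ids %||% paste0("seq", seq_along(records))
    records <- data.frame(id = as.character(ids), description = "",
                          residues = toupper(records),
                          stringsAsFactors = FALSE)
    class(records) <- c("seq_records", "data.frame")
  }
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$id)) stop("duplicate sequence id")
  if (nrow(records) < 2L) stop("an alignment needs at least 2 records")
  widths <- nchar(records$residues)
  if (length(unique(widths)) != 1L) {
    stop("aligned records must all have the same padded length")
  }
  sanitize_residues(records$residues, map_nonstandard = FALSE,
                    allow_gap = TRUE)
  structure(list(records = records, column_count = widths[[1]]),
            class = "aa_alignment")
}

#' Read an aligned FASTA file
#'
#' @inheritParams read_fasta
#' @return an `aa_alignment`.
#' @export
read_alignment <- function(path, map_nonstandard = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty input: no records in ", path)
  headers <- names(set)
  res <- toupper(as.character(set))
  if (map_nonstandard) {
    res <- sanitize_residues(res, map_nonstandard = TRUE, allow_gap = TRUE)
  }
  recs <- data.frame(id = sub("\\s.*$", "", headers),
                     description = ifelse(grepl("\\s", headers),
                                          sub("^\\S+\\s+", "", headers), ""),
                     residues = res, stringsAsFactors = FALSE)
  if (anyDuplicated(recs$id)) {
    stop("duplicate sequence id: ",
         paste(unique(recs$id[duplicated(recs$id)]), collapse = ", "))
  }
  class(recs) <- c("seq_records", "data.frame")
  alignment(recs)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an `aa_alignment`.
#' @param path output path.
#' @param wrap_width residues per line.
#' @export
write_alignment <- function(aln, path, wrap_width = 60) {
  stopifnot(inherits(aln, "aa_alignment"))
  recs <- aln$records
  set <- Biostrings::BStringSet(recs$residues)
  names(set) <- ifelse(nzchar(recs$description),
                       paste(recs$id, recs$description), recs$id)
  Biostrings::writeXStringSet(set, path, width = wrap_width)
  invisible(path)
}

#' Write a tabular report
#'
#' TSV with a header row; the convention for every report the pipeline
#' emits (call tables, census tables, filter and architecture reports).
#' @param df a data.frame.
#' @param path output path.
#' @export
write_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tabular report written by [write_report()]
#' @param path path to a TSV report.
#' @return a data.frame.
#' @export
read_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
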