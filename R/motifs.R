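# Motif location and the kinase filter cascade.
#
# Candidate sequences (profile-search hits) pass through, in order:
#   1. length filter (< min_length residues eliminated as truncated),
#   2. glycine-rich loop check (GXGXXG; >= 1 conserved template glycine),
#   3. catalytic-loop aspartate check (the catalytic base); its absence in
#      an otherwise kinase-like sequence flags a PKLNK,
#   4. RD status (arginine immediately preceding the catalytic aspartate).
# Motif positions are read off the profile-hit alignment path, not by regex
# scanning: the catalytic-loop consensus (HRDLKXXN) degenerates across
# subfamilies, and column-anchored checking is what profile annotation
# supports.

# sequence position aligned to a given profile column within a hit
# (NA if the column is outside the hit or aligned to a gap)
mapped_position <- function(hit, column) {
  i <- which(hit$path$profile_col == column)
  if (length(i) == 0L) return(NA_integer_)
  hit$path$seq_pos[[i]]
}

#' Check a glycine-rich loop window
#'
#' The GXGXXG template conserves glycines at positions 1, 3 and 6.
#'
#' @param window exactly 6 residues (the mapped glycine-loop span; gapped
#'   positions may be `-`).
#' @param min_conserved how many template glycines are required (1-3;
#'   default 1).
#' @return list with `matches` (logical) and `conserved_G_count` (0-3).
#' @export
check_glycine_loop <- function(window, min_conserved = 1) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  if (length(chars) != 6L) {
    stop("glycine-loop window must be exactly 6 residues, got ",
         length(chars))
  }
  count <- sum(chars[c(1, 3, 6)] == "G")
  list(matches = count >= min_conserved, conserved_G_count = count)
}

#' Locate kinase motifs through a profile hit
#'
#' Maps the master profile's annotated motif columns onto sequence
#' positions through the hit's alignment path.  If the catalytic aspartate
#' column aligns to a gap (deletion), the catalytic-loop annotation is
#' still emitted with `catalytic_D_present = FALSE`.
#'
#' @param record the scanned sequence (one `seq_records` row).
#' @param kinase_hit a `profile_hit` of `record` against `master_profile`.
#' @param master_profile a `kinase_profile` with `motif_columns` for
#'   `glycine_loop` and `catalytic_loop` and a `catalytic_D_column`.
#' @return a named list of motif annotations (`glycine_loop`,
#'   `catalytic_loop`).
#' @export
locate_motifs <- function(record, kinase_hit, master_profile) {
  if (!inherits(kinase_hit, "profile_hit") || is.null(kinase_hit$path)) {
    stop("malformed hit: no alignment path")
  }
  mc <- master_profile$motif_columns
  if (is.null(mc$glycine_loop) || is.null(mc$catalytic_loop) ||
      is.null(master_profile$catalytic_D_column)) {
    stop("master profile lacks motif annotations")
  }
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  window_of <- function(cols) {
    pos <- vapply(cols, function(cl) mapped_position(kinase_hit, cl),
                  integer(1))
    list(pos = pos,
         window = paste(ifelse(is.na(pos), "-", chars[pos]), collapse = ""))
  }
  span_of <- function(pos) {
    if (all(is.na(pos))) c(NA_integer_, NA_integer_)
    else c(min(pos, na.rm = TRUE), max(pos, na.rm = TRUE))
  }

  g_cols <- seq(mc$glycine_loop[[1]], mc$glycine_loop[[2]])
  g <- window_of(g_cols)
  g_count <- sum(strsplit(g$window, "")[[1]][c(1, 3, 6)] == "G")
  gly <- list(kind = "glycine_loop", seq_span = span_of(g$pos),
              matched = g$window, conserved_G_count = g_count)

  c_cols <- seq(mc$catalytic_loop[[1]], mc$catalytic_loop[[2]])
  cl <- window_of(c_cols)
  d_pos <- mapped_position(kinase_hit, master_profile$catalytic_D_column)
  d_present <- !is.na(d_pos) && chars[[d_pos]] == "D"
  r_pos <- mapped_position(kinase_hit, master_profile$catalytic_D_column - 1L)
  rd <- d_present && !is.na(r_pos) && chars[[r_pos]] == "R"
  cat_loop <- list(kind = "catalytic_loop", seq_span = span_of(cl$pos),
                   matched = cl$window, catalytic_D_present = d_present,
                   catalytic_D_position = d_pos, rd = rd)
  list(glycine_loop = gly, catalytic_loop = cat_loop)
}

#' Apply the kinase filter cascade to one candidate
#'
#' Evaluates length, glycine loop, catalytic aspartate and RD status in
#' order.  `accepted` requires all of length, glycine loop and catalytic D;
#' `pklnk` (protein-kinase-like non-kinase) requires a kinase-like sequence
#' (length, glycine loop, and a master-profile hit covering at least
#' `pklnk_min_coverage` of the profile) that lacks the catalytic aspartate.
#'
#' @inheritParams locate_motifs
#' @param min_length sequences shorter than this are eliminated as
#'   truncated (default 200).
#' @param glycine_min_conserved required conserved template glycines.
#' @param pklnk_min_coverage master-profile coverage required for PKLNK
#'   status (default 0.5).
#' @return a one-row data.frame of class `filter_verdict` with the fields
#'   of the filter report.
#' @export
apply_filter_cascade <- function(record, kinase_hit, master_profile,
                                 min_length = 200,
                                 glycine_min_conserved = 1,
                                 pklnk_min_coverage = 0.5) {
  len <- nchar(record$residues)
  long_enough <- len >= min_length
  motifs <- locate_motifs(record, kinase_hit, master_profile)
  has_gly <- motifs$glycine_loop$conserved_G_count >= glycine_min_conserved
  has_d <- motifs$catalytic_loop$catalytic_D_present
  rd <- motifs$catalytic_loop$rd
  accepted <- long_enough && has_gly && has_d
  pklnk <- long_enough && has_gly && !has_d &&
    kinase_hit$profile_coverage >= pklnk_min_coverage
  out <- data.frame(
    seq_id = record$id, length = len, long_enough = long_enough,
    has_glycine_loop = has_gly,
    glycine_window = motifs$glycine_loop$matched,
    conserved_G_count = motifs$glycine_loop$conserved_G_count,
    has_catalytic_D = has_d,
    catalytic_D_position = motifs$catalytic_loop$catalytic_D_position %||%
      NA_integer_,
    rd = rd, pklnk = pklnk, accepted = accepted,
    stringsAsFactors = FALSE)
  class(out) <- c("filter_verdict", "data.frame")
  out
}
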