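# Pathway homolog-presence mapping: classify pathway-template proteins as
# having a close, remote or no homolog in a target proteome.
#
# Each template is turned into a single-sequence profile and searched
# against the proteome by local alignment.  The best hit at the primary
# E-value cutoff (default 1e-4) is taken; with none, a relaxed second pass
# (default 1e-3) rescues remote homologs.  A homolog is "close" when
# identity > 30% and template coverage > 0.70 (both strict), "remote" when
# a significant hit exists below those levels, and the template is
# "absent" with no hit in either pass.

#' Map pathway templates onto a proteome
#'
#' @param templates a `seq_records` data.frame of pathway template
#'   proteins.
#' @param proteome a `seq_records` data.frame (the target proteome).
#' @param primary_evalue first-pass E-value cutoff (default 1e-4).
#' @param relaxed_evalue rescue-pass cutoff (default 1e-3).
#' @param identity_threshold strict identity bound for `close` (default
#'   30).
#' @param coverage_threshold strict template-coverage bound for `close`
#'   (default 0.70); coverage is the aligned fraction of the template
#'   length.
#' @param calibration_seed seed for per-template E-value calibration.
#' @param decoy_count decoys per calibration.
#' @param config pipeline config (gap costs).
#' @return data.frame with one row per template: `template_id`,
#'   `best_target_id`, `evalue`, `percent_identity`, `coverage`, `pass`
#'   (`primary`/`relaxed`/`none`) and `presence_class`
#'   (`close`/`remote`/`absent`).
#' @export
map_pathway <- function(templates, proteome, primary_evalue = 1e-4,
                        relaxed_evalue = 1e-3, identity_threshold = 30,
                        coverage_threshold = 0.70, calibration_seed = 1,
                        decoy_count = 200, config = default_config()) {
  if (!is.data.frame(templates) || nrow(templates) == 0L) {
    stop("empty input: no pathway templates")
  }
  stopifnot(nrow(proteome) > 0)
  rows <- lapply(seq_len(nrow(templates)), function(i) {
    tmpl <- templates[i, ]
    prof <- sequence_profile(tmpl)
    prof$calibration <- calibrate_evalue(
      prof, decoy_length = max(nchar(tmpl$residues), 100),
      decoy_count = decoy_count, seed = calibration_seed + i,
      gap_open = config$gap_open, gap_extend = config$gap_extend)
    hits <- list()
    for (j in seq_len(nrow(proteome))) {
      hits <- c(hits, scan_profile(prof, proteome[j, ],
                                   gap_open = config$gap_open,
                                   gap_extend = config$gap_extend,
                                   max_evalue = relaxed_evalue,
                                   max_hits = 1))
    }
    best_at <- function(cutoff) {
      ok <- Filter(function(h) h$evalue <= cutoff, hits)
      if (length(ok) == 0L) return(NULL)
      ev <- vapply(ok, `[[`, 0, "evalue")
      ident <- vapply(ok, `[[`, 0, "percent_identity")
      ok[[order(ev, -ident)[[1]]]]
    }
    best <- best_at(primary_evalue)
    pass <- if (!is.null(best)) "primary" else {
      best <- best_at(relaxed_evalue)
      if (!is.null(best)) "relaxed" else "none"
    }
    if (is.null(best)) {
      return(data.frame(template_id = tmpl$id,
                        best_target_id = NA_character_,
                        evalue = NA_real_, percent_identity = NA_real_,
                        coverage = NA_real_, pass = "none",
                        presence_class = "absent",
                        stringsAsFactors = FALSE))
    }
    cls <- if (best$percent_identity > identity_threshold &&
               best$profile_coverage > coverage_threshold) "close"
           else "remote"
    data.frame(template_id = tmpl$id, best_target_id = best$seq_id,
               evalue = best$evalue,
               percent_identity = best$percent_identity,
               coverage = best$profile_coverage, pass = pass,
               presence_class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise pathway presence classes
#'
#' @param annotations data.frame from [map_pathway()].
#' @return list with `counts` (named integer vector over
#'   close/remote/absent) and `close_fraction` (3 decimals).
#' @export
pathway_summary <- function(annotations) {
  stopifnot(nrow(annotations) > 0)
  counts <- table(factor(annotations$presence_class,
                         levels = c("close", "remote", "absent")))
  list(counts = setNames(as.integer(counts), names(counts)),
       close_fraction = round_half_up(counts[["close"]] /
                                        nrow(annotations), 3))
}

#' Export pathway classes as a color edge list
#'
#' `template -> color` rows (green/yellow/red for close/remote/absent) for
#' external network rendering.
#' @param annotations data.frame from [map_pathway()].
#' @export
pathway_color_edges <- function(annotations) {
  color <- c(close = "green", remote = "yellow", absent = "red")
  data.frame(template_id = annotations$template_id,
             color = unname(color[annotations$presence_class]),
             stringsAsFactors = FALSE)
}
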