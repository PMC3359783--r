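# Hanks-Hunter group/subfamily assignment and kinome census statistics.
#
# A sequence is associated with a subfamily when a subfamily-profile hit
# shows percent identity strictly greater than the identity threshold
# (default 30) and profile coverage of at least the coverage threshold
# (default 0.70).  The winning subfamily's declared parent group gives the
# group; candidates failing every subfamily rule fall into
# "Other"/"Unclassified".

HANKS_HUNTER_GROUPS <- c("AGC", "CMGC", "CAMK", "STE", "CK1", "TK", "TKL")

#' Default pipeline configuration
#'
#' Numeric settings of the annotation protocol: profile-search E-value
#' cutoff 1e-4 (relaxed pass 1e-3 for pathway mapping), minimum sequence
#' length 200, subfamily identity threshold 30 (strict) and profile
#' coverage threshold 0.70, at least 1 conserved glycine in the
#' glycine-rich loop, and the hydropathy transmembrane predictor's window
#' (19), threshold (1.6) and merge gap (5).
#'
#' @param ... named overrides of any default.
#' @return a list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    evalue_cutoff = 1e-4,
    relaxed_evalue = 1e-3,
    min_length = 200,
    identity_threshold = 30,
    coverage_threshold = 0.70,
    glycine_min_conserved = 1,
    pklnk_min_coverage = 0.5,
    identity_reference = "consensus",   # or "members"
    tm_window = 19,
    tm_threshold = 1.6,
    tm_min_gap = 5,
    gap_open = 11,
    gap_extend = 1,
    max_hits = 4,
    seed = 1
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$identity_threshold >= 0, cfg$identity_threshold <= 100,
            cfg$coverage_threshold >= 0, cfg$coverage_threshold <= 1,
            cfg$glycine_min_conserved %in% 1:3,
            cfg$evalue_cutoff > 0, cfg$min_length >= 0)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Assign a kinase to its subfamily and group
#'
#' Candidate hits must have `percent_identity > identity_threshold`
#' (strict) and `profile_coverage >= coverage_threshold`.  The best
#' candidate — by identity, then coverage, then score, then lexicographic
#' profile name — sets the subfamily and its parent group; with no
#' candidate the call is group `"Other"`, subfamily `"Unclassified"`.
#'
#' @param verdict a `filter_verdict` (the sequence must be accepted or a
#'   PKLNK).
#' @param hits list of subfamily `profile_hit`s for this sequence.
#' @param manifest data.frame mapping subfamily profile `name` to parent
#'   `group` (a profile library manifest).
#' @param identity_threshold strict lower bound on percent identity
#'   (default 30).
#' @param coverage_threshold non-strict lower bound on profile coverage
#'   (default 0.70).
#' @return list with `group`, `subfamily`, `best_hit` (or `NULL`).
#' @export
assign_subfamily <- function(verdict, hits, manifest,
                             identity_threshold = 30,
                             coverage_threshold = 0.70) {
  if (length(hits)) {
    unknown <- setdiff(vapply(hits, `[[`, "", "profile_name"),
                       manifest$name)
    if (length(unknown)) {
      stop("library inconsistency: hits reference unknown profile(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  cand <- Filter(function(h) {
    h$percent_identity > identity_threshold &&
      h$profile_coverage >= coverage_threshold
  }, hits)
  if (length(cand) == 0L) {
    return(list(group = "Other", subfamily = "Unclassified",
                best_hit = NULL))
  }
  ident <- vapply(cand, `[[`, 0, "percent_identity")
  cov <- vapply(cand, `[[`, 0, "profile_coverage")
  score <- vapply(cand, `[[`, 0, "score")
  nm <- vapply(cand, `[[`, "", "profile_name")
  best <- cand[[order(-ident, -cov, -score, nm)[[1]]]]
  row <- manifest[manifest$name == best$profile_name, ]
  list(group = row$group[[1]], subfamily = row$label[[1]], best_hit = best)
}

#' Classify a proteome
#'
#' Runs the full annotation protocol over every sequence: master kinase
#' profile scan at the E-value cutoff, filter cascade (length, glycine
#' loop, catalytic aspartate, RD), subfamily assignment by the
#' identity/coverage rule, and (optionally) twin-kinase, transmembrane and
#' receptor flags.  Deterministic given the calibrated library and config.
#'
#' @param records a `seq_records` proteome.
#' @param library a profile library as returned by [generate_library()] or
#'   assembled manually: a list with calibrated `master` profile,
#'   `subfamilies` (named list of calibrated profiles) and `manifest`.
#' @param config a [default_config()] list.
#' @param architecture if `TRUE` (default), also compute twin/TM/receptor
#'   flags for accepted calls.
#' @return a data.frame of kinase calls, one row per input sequence.
#' @export
classify_proteome <- function(records, library, config = default_config(),
                              architecture = TRUE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("empty input: no sequences to classify")
  }
  master <- library$master
  if (is.null(master$calibration)) {
    stop("library master profile is not calibrated")
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    classify_one(rec, library, config, architecture)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_call <- function(rec) {
  data.frame(
    seq_id = rec$id, length = nchar(rec$residues), candidate = FALSE,
    long_enough = NA, has_glycine_loop = NA, has_catalytic_D = NA,
    accepted = FALSE, pklnk = FALSE, rd = FALSE,
    group = NA_character_, subfamily = NA_character_,
    identity = NA_real_, coverage = NA_real_, evalue = NA_real_,
    score_bits = NA_real_, kinase_domains = 0L, twin = FALSE,
    tm_segment_count = 0L, receptor = FALSE, stringsAsFactors = FALSE)
}

classify_one <- function(rec, library, config, architecture) {
  master_hits <- scan_profile(
    library$master, rec, gap_open = config$gap_open,
    gap_extend = config$gap_extend, max_evalue = config$evalue_cutoff,
    max_hits = config$max_hits)
  if (length(master_hits) == 0L) return(empty_call(rec))
  best <- master_hits[[1]]
  verdict <- apply_filter_cascade(
    rec, best, library$master, min_length = config$min_length,
    glycine_min_conserved = config$glycine_min_conserved,
    pklnk_min_coverage = config$pklnk_min_coverage)

  group <- NA_character_; subfamily <- NA_character_
  ident <- NA_real_; cov <- NA_real_; ev <- NA_real_; sb <- NA_real_
  if (verdict$accepted || verdict$pklnk) {
    sub_hits <- list()
    for (p in library$subfamilies) {
      sub_hits <- c(sub_hits, scan_profile(
        p, rec, gap_open = config$gap_open, gap_extend = config$gap_extend,
        max_evalue = config$evalue_cutoff, max_hits = 1))
    }
    if (identical(config$identity_reference, "members")) {
      sub_hits <- lapply(sub_hits, function(h) {
        p <- library$subfamilies[[h$profile_name]]
        mi <- member_identity(p, rec)
        if (!is.na(mi)) h$percent_identity <- mi
        h
      })
    }
    asg <- assign_subfamily(verdict, sub_hits, library$manifest,
                            identity_threshold = config$identity_threshold,
                            coverage_threshold = config$coverage_threshold)
    group <- asg$group; subfamily <- asg$subfamily
    if (!is.null(asg$best_hit)) {
      ident <- asg$best_hit$percent_identity
      cov <- asg$best_hit$profile_coverage
      ev <- asg$best_hit$evalue
      sb <- asg$best_hit$score_bits
    }
  }

  twin <- FALSE; n_dom <- length(master_hits)
  tm_count <- 0L; receptor <- FALSE
  if (architecture && (verdict$accepted || verdict$pklnk)) {
    competent <- vapply(master_hits, function(h) {
      h$profile_coverage >= config$coverage_threshold &&
        locate_motifs(rec, h, library$master)$catalytic_loop$
          catalytic_D_present
    }, logical(1))
    twin <- verdict$accepted && sum(competent) >= 2L
    tm <- predict_tm_segments(rec, window = config$tm_window,
                              threshold = config$tm_threshold,
                              min_gap = config$tm_min_gap)
    tm_count <- nrow(tm)
    receptor <- verdict$accepted && tm_count >= 1L
  }

  data.frame(
    seq_id = rec$id, length = verdict$length, candidate = TRUE,
    long_enough = verdict$long_enough,
    has_glycine_loop = verdict$has_glycine_loop,
    has_catalytic_D = verdict$has_catalytic_D,
    accepted = verdict$accepted, pklnk = verdict$pklnk, rd = verdict$rd,
    group = group, subfamily = subfamily,
    identity = ident, coverage = cov, evalue = ev, score_bits = sb,
    kinase_domains = n_dom, twin = twin,
    tm_segment_count = tm_count, receptor = receptor,
    stringsAsFactors = FALSE)
}

#' Kinome census
#'
#' Counts and percentages of accepted kinases per group (including
#' `"Other"`) or per subfamily.  Percentages are half-up rounded to 2
#' decimals; the denominator is the number of accepted calls.
#'
#' @param calls a call table from [classify_proteome()].
#' @param organism organism tag for the table.
#' @param level `"group"` or `"subfamily"`.
#' @return a list of class `distribution_table` with `organism`, `level`,
#'   `counts`, `percentages` and `total`.
#' @export
census <- function(calls, organism, level = c("group", "subfamily")) {
  level <- match.arg(level)
  stopifnot(nrow(calls) > 0)
  acc <- calls[calls$accepted, , drop = FALSE]
  labs <- if (level == "group") {
    factor(acc$group, levels = c(HANKS_HUNTER_GROUPS, "Other"))
  } else {
    factor(acc$subfamily)
  }
  counts <- table(labs)
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * as.numeric(counts) / total, 2)
         else rep(0, length(counts))
  structure(list(organism = organism, level = level,
                 counts = setNames(as.integer(counts), names(counts)),
                 percentages = setNames(pct, names(counts)),
                 total = total),
            class = "distribution_table")
}

#' @export
print.distribution_table <- function(x, ...) {
  cat(sprintf("<distribution_table> %s (%s level, %d classified)\n",
              x$organism, x$level, x$total))
  print(data.frame(label = names(x$counts), count = unname(x$counts),
                   percent = unname(x$percentages)))
  invisible(x)
}

#' Convert a distribution table to a data.frame report
#' @param x a `distribution_table`.
#' @param ... unused.
#' @export
as.data.frame.distribution_table <- function(x, ...) {
  data.frame(organism = x$organism, level = x$level,
             label = names(x$counts), count = unname(x$counts),
             percent = unname(x$percentages), stringsAsFactors = FALSE)
}

#' Over-/under-representation across organisms
#'
#' Compares one focal organism's distribution against the others.  A label
#' is flagged `over` when the focal percentage is strictly greatest across
#' all organisms and `under` when strictly least; labels absent from an
#' organism count as 0.00%.
#'
#' @param tables list of `distribution_table`s at the same level.
#' @param reference_organism the focal organism (must be among the tables).
#' @return data.frame with one row per label: the focal percentage, each
#'   other organism's percentage, and a `status` of `over`/`under`/`none`.
#' @export
compare_distributions <- function(tables, reference_organism) {
  stopifnot(length(tables) >= 2)
  levels <- unique(vapply(tables, `[[`, "", "level"))
  if (length(levels) != 1L) {
    stop("level mismatch: all tables must be at the same level")
  }
  orgs <- vapply(tables, `[[`, "", "organism")
  if (!reference_organism %in% orgs) {
    stop("reference organism not among the tables: ", reference_organism)
  }
  labels <- sort(unique(unlist(lapply(tables, function(t)
    names(t$percentages)))))
  pct <- sapply(tables, function(t) {
    p <- t$percentages[labels]
    p[is.na(p)] <- 0
    p
  })
  if (is.null(dim(pct))) pct <- matrix(pct, nrow = length(labels))
  colnames(pct) <- orgs
  rownames(pct) <- labels
  focal <- pct[, reference_organism]
  others <- pct[, setdiff(orgs, reference_organism), drop = FALSE]
  status <- ifelse(focal > apply(others, 1, max), "over",
            ifelse(focal < apply(others, 1, min), "under", "none"))
  out <- data.frame(label = labels, focal = unname(focal),
                    stringsAsFactors = FALSE)
  for (o in colnames(others)) out[[o]] <- unname(others[, o])
  out$status <- unname(status)
  out
}

#' Flag group outliers by within-group identity
#'
#' Optional post-classification step: an accepted call is an outlier when
#' its catalytic-domain identity to every other member of its assigned
#' group is below `identity_threshold` (single-linkage singleton at the
#' corresponding distance).
#'
#' @param calls call table (accepted calls with groups).
#' @param records the proteome the calls came from.
#' @param library profile library (for catalytic-domain extraction).
#' @param identity_threshold percent identity (default 25).
#' @return `calls` with an added logical `group_outlier` column.
#' @export
flag_group_outliers <- function(calls, records, library,
                                identity_threshold = 25) {
  calls$group_outlier <- FALSE
  acc <- which(calls$accepted & !is.na(calls$group) &
                 calls$group != "Other")
  doms <- catalytic_domain_records(records[match(calls$seq_id[acc],
                                                 records$id), ],
                                   library)
  for (g in unique(calls$group[acc])) {
    idx <- acc[calls$group[acc] == g]
    if (length(idx) < 2L) { calls$group_outlier[idx] <- TRUE; next }
    sub <- doms[match(calls$seq_id[idx], doms$id), ]
    d <- identity_distance_matrix(sub)
    part <- single_linkage_clusters(d, 1 - identity_threshold / 100)
    singletons <- unlist(part[lengths(part) == 1L])
    calls$group_outlier[idx[calls$seq_id[idx] %in% singletons]] <- TRUE
  }
  calls
}
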