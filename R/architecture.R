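# Domain architecture, twin-kinase detection, transmembrane prediction and
# receptor flagging.

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector over the 20 standard residues; `X` scores 0.
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
  M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3, X = 0)

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Mean Kyte-Doolittle hydropathy over a sliding window; maximal runs of
#' window centers above the threshold are merged when separated by fewer
#' than `min_gap` centers, and each reported span extends to the window
#' edges (so spans are at least `window` residues long).
#'
#' @param record one `seq_records` row.
#' @param window odd window length (default 19).
#' @param threshold mean hydropathy above which a center counts (default
#'   1.6).
#' @param min_gap runs closer than this many positions are merged.
#' @return data.frame with columns `start`, `end` (1-based inclusive);
#'   empty for sequences shorter than the window.
#' @export
predict_tm_segments <- function(record, window = 19, threshold = 1.6,
                                min_gap = 5) {
  stopifnot(window %% 2 == 1)
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < window) {
    message("sequence ", record$id, " shorter than hydropathy window; ",
            "no TM prediction")
    return(empty)
  }
  h <- KYTE_DOOLITTLE[chars]
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  half <- (window - 1) / 2
  centers <- which(!is.na(means) & means > threshold)
  if (length(centers) == 0L) return(empty)
  # split into runs, merging runs with gaps < min_gap
  breaks <- which(diff(centers) - 1 >= min_gap)
  starts <- centers[c(1, breaks + 1)]
  ends <- centers[c(breaks, length(centers))]
  data.frame(start = pmax(1L, starts - half),
             end = pmin(n, ends + half))
}

#' Assign co-occurring domains
#'
#' Collects all domain-profile hits at or below the E-value cutoff and
#' resolves overlaps greedily by descending score (ties: longer hit, then
#' leftmost, then profile name); hits overlapping by at most
#' `overlap_tolerance` residues are both kept (domain boundaries are
#' fuzzy).  Optionally adds hydropathy-predicted TM segments.
#'
#' @param record one `seq_records` row.
#' @param domain_profiles named list of calibrated `kinase_profile`s
#'   (level `"domain"`; may include the master kinase profile).
#' @param evalue_cutoff report hits at E <= this (default 1e-4).
#' @param overlap_tolerance residues of overlap tolerated (default 10).
#' @param max_hits_per_profile non-overlapping hits collected per profile.
#' @param tm if `TRUE`, also predict TM segments.
#' @param config pipeline config supplying gap and TM parameters.
#' @return a list of class `domain_architecture` with `seq_id`, `domains`
#'   (data.frame `label`, `start`, `end`, `score_bits`, `evalue`, ordered
#'   N to C) and `tm_segments`.
#' @export
assign_domains <- function(record, domain_profiles, evalue_cutoff = 1e-4,
                           overlap_tolerance = 10,
                           max_hits_per_profile = 3, tm = TRUE,
                           config = default_config()) {
  if (length(domain_profiles) == 0L) stop("empty domain library")
  hits <- list()
  for (p in domain_profiles) {
    hits <- c(hits, scan_profile(p, record, gap_open = config$gap_open,
                                 gap_extend = config$gap_extend,
                                 max_evalue = evalue_cutoff,
                                 max_hits = max_hits_per_profile))
  }
  doms <- resolve_overlaps(hits, overlap_tolerance)
  tm_seg <- if (tm) {
    predict_tm_segments(record, config$tm_window, config$tm_threshold,
                        config$tm_min_gap)
  } else data.frame(start = integer(0), end = integer(0))
  structure(list(seq_id = record$id, domains = doms, tm_segments = tm_seg),
            class = "domain_architecture")
}

resolve_overlaps <- function(hits, overlap_tolerance = 10) {
  if (length(hits) == 0L) {
    return(data.frame(label = character(0), start = integer(0),
                      end = integer(0), score_bits = numeric(0),
                      evalue = numeric(0)))
  }
  df <- data.frame(
    label = vapply(hits, `[[`, "", "profile_label"),
    name = vapply(hits, `[[`, "", "profile_name"),
    start = vapply(hits, function(h) h$seq_span[[1]], 0),
    end = vapply(hits, function(h) h$seq_span[[2]], 0),
    score = vapply(hits, `[[`, 0, "score"),
    score_bits = vapply(hits, `[[`, 0, "score_bits"),
    evalue = vapply(hits, `[[`, 0, "evalue"),
    stringsAsFactors = FALSE)
  df <- df[order(-df$score, -(df$end - df$start), df$start, df$name), ]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    ov <- pmin(kept$end, df$end[[i]]) - pmax(kept$start, df$start[[i]]) + 1
    if (all(ov <= overlap_tolerance)) kept <- rbind(kept, df[i, ])
  }
  kept <- kept[order(kept$start), c("label", "start", "end",
                                    "score_bits", "evalue")]
  rownames(kept) <- NULL
  kept
}

#' Detect twin-kinase proteins
#'
#' A twin kinase carries two complete, catalytically competent kinase
#' domains: at least two non-overlapping master-profile hits, each with
#' profile coverage of at least `coverage_threshold` and the catalytic
#' aspartate present under its own motif mapping.  Janus-like proteins
#' (second domain lacking the aspartate) are not twins.
#'
#' @param record one `seq_records` row.
#' @param master_profile calibrated master kinase profile with motif
#'   annotations.
#' @param evalue_cutoff profile-search cutoff.
#' @param coverage_threshold per-domain coverage requirement (default
#'   0.70).
#' @param config pipeline config (gap costs).
#' @return list with `twin` (logical) and `detail` (per-hit data.frame:
#'   span, coverage, identity, catalytic D, competence).
#' @export
detect_twin_kinase <- function(record, master_profile,
                               evalue_cutoff = 1e-4,
                               coverage_threshold = 0.70,
                               config = default_config()) {
  hits <- scan_profile(master_profile, record, gap_open = config$gap_open,
                       gap_extend = config$gap_extend,
                       max_evalue = evalue_cutoff, max_hits = 4)
  if (length(hits) == 0L) {
    return(list(twin = FALSE,
                detail = data.frame(start = integer(0), end = integer(0),
                                    coverage = numeric(0),
                                    identity = numeric(0),
                                    catalytic_D = logical(0),
                                    competent = logical(0))))
  }
  detail <- do.call(rbind, lapply(hits, function(h) {
    d <- locate_motifs(record, h, master_profile)$catalytic_loop$
      catalytic_D_present
    data.frame(start = h$seq_span[[1]], end = h$seq_span[[2]],
               coverage = h$profile_coverage,
               identity = h$percent_identity, catalytic_D = d,
               competent = d && h$profile_coverage >= coverage_threshold)
  }))
  detail <- detail[order(detail$start), ]
  rownames(detail) <- NULL
  list(twin = sum(detail$competent) >= 2L, detail = detail)
}

#' Flag receptor kinases
#'
#' A kinase with at least one predicted transmembrane segment is a
#' receptor kinase (a receptor tyrosine kinase when its group is TK).
#'
#' @param call one row of a call table.
#' @param architecture a `domain_architecture` (or any list with a
#'   `tm_segments` data.frame).
#' @return the call row with `tm_segment_count` and `receptor` updated.
#' @export
flag_receptor <- function(call, architecture) {
  call$tm_segment_count <- nrow(architecture$tm_segments)
  call$receptor <- isTRUE(call$accepted) && call$tm_segment_count >= 1L
  call
}

#' Architecture report string
#'
#' `label:start-end:score` segments joined by `+`, N to C (1-based
#' inclusive coordinates, as in all reports).
#' @param architecture a `domain_architecture`.
#' @export
format_architecture <- function(architecture) {
  d <- architecture$domains
  if (nrow(d) == 0L) return("")
  paste(sprintf("%s:%d-%d:%.1f", d$label, d$start, d$end, d$score_bits),
        collapse = "+")
}
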