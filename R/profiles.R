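# Position-specific scoring matrices and the local profile scanner.
#
# Profiles are per-column log-odds matrices in half-bit units:
#   s(col, a) = 2 * log2(f_a / p_a)
# with observed frequencies regularised by background-frequency pseudocounts,
#   f_a = (n_a + w * p_a) / (N + w),
# where N is the number of counted residues in the column and w the
# pseudocount weight.  X is scored 0 in every column.  Searching is local
# dynamic programming with affine gaps (open 11, extend 1 by default, in
# half-bit units) and E-values from an empirical Gumbel calibration on
# background decoys, E = K * m * n * exp(-lambda * S).

#' Build a profile from a seed alignment
#'
#' Columns with more than `max_gap_fraction` gaps are dropped before scoring;
#' motif annotations survive the dropping by index remapping.  The consensus
#' is the highest-frequency residue of each retained column.
#'
#' @param aln an [alignment()] with at least 2 sequences.
#' @param name unique profile name.
#' @param level one of `"group"`, `"subfamily"`, `"domain"`.
#' @param label group/subfamily/domain label carried into classifications.
#' @param pseudocount_weight total pseudocount mass `w` (default 1).
#' @param background named background frequencies over [AA_STANDARD]
#'   (default uniform 0.05).
#' @param motif_columns optional named list of `c(start, end)` 1-based
#'   column ranges in the *input* alignment, keyed `glycine_loop` /
#'   `catalytic_loop`.
#' @param catalytic_D_column optional 1-based input column of the catalytic
#'   aspartate.
#' @param max_gap_fraction columns with a greater gap fraction are dropped.
#' @param keep_seeds if `TRUE`, the ungapped seed sequences are stored so
#'   identity can alternatively be measured against seed members.
#' @return an object of class `kinase_profile`.
#' @export
build_profile <- function(aln, name, level = c("subfamily", "group", "domain"),
                          label = name, pseudocount_weight = 1,
                          background = uniform_background(),
                          motif_columns = NULL, catalytic_D_column = NULL,
                          max_gap_fraction = 0.5, keep_seeds = FALSE) {
  level <- match.arg(level)
  if (!inherits(aln, "aa_alignment")) {
    stop("`aln` must be an aa_alignment (use alignment())")
  }
  if (nrow(aln$records) < 2L) {
    stop("insufficient seed: a profile needs an alignment of >= 2 sequences")
  }
  mat <- do.call(rbind, strsplit(aln$records$residues, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0L) stop("empty profile: all columns are gapped")
  new_index <- integer(ncol(mat))        # 0 for dropped columns
  new_index[keep] <- seq_along(keep)

  remap_range <- function(rng) {
    cols <- intersect(seq(rng[[1]], rng[[2]]), keep)
    if (length(cols) == 0L) return(NULL)
    c(min(new_index[cols]), max(new_index[cols]))
  }
  motifs <- NULL
  if (!is.null(motif_columns)) {
    motifs <- Filter(Negate(is.null), lapply(motif_columns, remap_range))
  }
  d_col <- NULL
  if (!is.null(catalytic_D_column)) {
    if (new_index[catalytic_D_column] == 0L) {
      warning("catalytic D column was dropped (gapped); profile has no ",
              "catalytic_D_column")
    } else {
      d_col <- new_index[catalytic_D_column]
    }
  }

  background <- background[AA_STANDARD]
  w <- pseudocount_weight
  score_one <- function(colchars) {
    counts <- table(factor(colchars, levels = AA_STANDARD))  # X, '-' ignored
    n <- sum(counts)
    f <- (as.numeric(counts) + w * background) / (n + w)
    list(scores = 2 * log2(f / background),
         consensus = AA_STANDARD[which.max(f)])
  }
  cols <- lapply(keep, function(k) score_one(mat[, k]))
  scores <- do.call(rbind, lapply(cols, `[[`, "scores"))
  colnames(scores) <- AA_STANDARD
  consensus <- paste(vapply(cols, `[[`, "", "consensus"), collapse = "")

  seeds <- NULL
  if (keep_seeds) {
    seeds <- aln$records
    seeds$residues <- gsub("-", "", seeds$residues, fixed = TRUE)
  }
  structure(list(name = name, level = level, label = label,
                 scores = scores, consensus = consensus,
                 motif_columns = motifs, catalytic_D_column = d_col,
                 background = background, n_seeds = nrow(aln$records),
                 pseudocount_weight = w, seeds = seeds,
                 calibration = NULL),
            class = "kinase_profile")
}

#' Build a single-sequence profile
#'
#' Degenerate profile used for sequence-vs-sequence searching (pathway
#' homolog mapping): same log-odds machinery with seed count 1.
#'
#' @param record one row of a `seq_records` data.frame (or a list with
#'   `id` and `residues`).
#' @inheritParams build_profile
#' @export
sequence_profile <- function(record, name = record$id, level = "domain",
                             label = name, pseudocount_weight = 1,
                             background = uniform_background()) {
  background <- background[AA_STANDARD]
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  w <- pseudocount_weight
  score_one <- function(ch) {
    counts <- as.numeric(AA_STANDARD == ch)
    f <- (counts + w * background) / (sum(counts) + w)
    2 * log2(f / background)
  }
  scores <- do.call(rbind, lapply(chars, score_one))
  colnames(scores) <- AA_STANDARD
  consensus <- paste(ifelse(chars %in% AA_STANDARD, chars,
                            AA_STANDARD[[1]]), collapse = "")
  structure(list(name = name, level = level, label = label,
                 scores = scores, consensus = consensus,
                 motif_columns = NULL, catalytic_D_column = NULL,
                 background = background, n_seeds = 1L,
                 pseudocount_weight = w, seeds = NULL, calibration = NULL),
            class = "kinase_profile")
}

#' @export
print.kinase_profile <- function(x, ...) {
  cat(sprintf("<kinase_profile> %s (%s: %s), %d columns, %d seeds%s\n",
              x$name, x$level, x$label, nrow(x$scores), x$n_seeds,
              if (is.null(x$calibration)) ", uncalibrated"
              else sprintf(", lambda=%.4f K=%.3g",
                           x$calibration$lambda, x$calibration$K)))
  invisible(x)
}

n_columns <- function(profile) nrow(profile$scores)

# score matrix with the X column (all zero) appended
scores_with_x <- function(profile) {
  cbind(profile$scores, X = 0)
}

# -- E-value calibration -----------------------------------------------------

# method-of-moments Gumbel fit; returns location mu and scale-inverse lambda
gumbel_fit <- function(scores) {
  s <- var(scores)
  if (!is.finite(s) || s <= 0) {
    stop("calibration failure: degenerate (zero-variance) score distribution")
  }
  lambda <- pi / (sqrt(6 * s))
  mu <- mean(scores) - 0.5772156649015329 / lambda
  list(lambda = lambda, mu = mu)
}

#' Calibrate profile E-values on background decoys
#'
#' Scans `decoy_count` i.i.d. background-distributed decoy sequences and
#' fits Gumbel parameters (lambda, K) to the maximal-score distribution by
#' the method of moments, so that `E = K * m * n * exp(-lambda * S)` for a
#' raw half-bit score `S`, profile length `m` and query length `n`.
#' Deterministic given `seed`.
#'
#' @param profile a `kinase_profile`.
#' @param decoy_length length of each decoy sequence.
#' @param decoy_count number of decoys (>= 200).
#' @param seed RNG seed.
#' @param gap_open,gap_extend affine gap costs (half-bits).
#' @return an object of class `evalue_calibration` with fields `lambda`,
#'   `K`, `decoy_count`, `decoy_length`, `seed`.
#' @export
calibrate_evalue <- function(profile, decoy_length = 350, decoy_count = 200,
                             seed = 1, gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(profile, "kinase_profile"))
  if (decoy_count < 200) stop("decoy_count must be >= 200")
  S <- scores_with_x(profile)
  best <- with_seed(seed, {
    vapply(seq_len(decoy_count), function(i) {
      decoy <- sample(seq_along(AA_STANDARD), decoy_length, replace = TRUE,
                      prob = profile$background)
      hits <- .profile_scan_cpp(S, decoy - 1L, gap_open, gap_extend,
                                -Inf, 1L)
      hits[[1]]$score
    }, numeric(1))
  })
  fit <- gumbel_fit(best)
  K <- exp(fit$lambda * fit$mu) / (n_columns(profile) * decoy_length)
  structure(list(lambda = fit$lambda, K = K,
                 decoy_count = decoy_count, decoy_length = decoy_length,
                 seed = seed, gap_open = gap_open, gap_extend = gap_extend),
            class = "evalue_calibration")
}

#' Attach a calibration to a profile
#' @param profile a `kinase_profile`.
#' @param ... passed to [calibrate_evalue()].
#' @return the profile with `$calibration` set.
#' @export
calibrate_profile <- function(profile, ...) {
  profile$calibration <- calibrate_evalue(profile, ...)
  profile
}

evalue_of <- function(calibration, m, n, raw_score) {
  calibration$K * m * n * exp(-calibration$lambda * raw_score)
}

# -- scanning ----------------------------------------------------------------

#' Scan a sequence with a profile
#'
#' Local dynamic programming of the sequence against the profile columns
#' with affine gaps.  All non-overlapping local optima above the reporting
#' threshold are returned (greedy by score; covered sequence positions are
#' masked between iterations), sorted by score descending.
#'
#' Percent identity is measured against the profile consensus over aligned
#' (non-gap) pairs; profile coverage is the fraction of profile columns
#' aligned to a residue.
#'
#' @param profile a `kinase_profile`.
#' @param record one row of a `seq_records` data.frame.
#' @param gap_open,gap_extend affine gap costs in half-bits.
#' @param calibration an `evalue_calibration`; defaults to the profile's
#'   own.  Required unless `min_raw_score` is given.
#' @param max_evalue reporting E-value threshold (default 10).
#' @param max_hits maximum number of non-overlapping hits.
#' @param min_raw_score optional raw-score reporting threshold; when given
#'   without a calibration, hits carry `evalue = NA`.
#' @return a list of `profile_hit` objects (possibly empty); each has
#'   `seq_id`, `profile_name`, `score` (raw half-bits), `score_bits`,
#'   `evalue`, `percent_identity`, `profile_coverage`, `seq_span`,
#'   `profile_span` (both 1-based inclusive) and `path` (a data.frame with
#'   columns `profile_col`, `seq_pos`; `NA` marks a gap).
#' @export
scan_profile <- function(profile, record, gap_open = 11, gap_extend = 1,
                         calibration = NULL, max_evalue = 10,
                         max_hits = 5, min_raw_score = NULL) {
  stopifnot(inherits(profile, "kinase_profile"))
  calibration <- calibration %||% profile$calibration
  if (is.null(calibration) && is.null(min_raw_score)) {
    stop("calibration missing for profile '", profile$name,
         "': calibrate with calibrate_profile() or give min_raw_score")
  }
  n <- nchar(record$residues)
  m <- n_columns(profile)
  if (n == 0L) stop("empty sequence")
  if (is.null(min_raw_score)) {
    # raw score at which E = max_evalue
    min_raw_score <- (log(calibration$K * m * n) - log(max_evalue)) /
      calibration$lambda
    min_raw_score <- max(min_raw_score, 1e-9)
  }
  codes <- encode_residues(record$residues)
  raw <- .profile_scan_cpp(scores_with_x(profile), codes - 1L,
                           gap_open, gap_extend, min_raw_score,
                           as.integer(max_hits))
  cons <- strsplit(profile$consensus, "", fixed = TRUE)[[1]]
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  hits <- lapply(raw, function(h) {
    pp <- h$path_profile
    ps <- h$path_seq
    aligned <- !is.na(pp) & !is.na(ps)
    ident <- 100 * sum(chars[ps[aligned]] == cons[pp[aligned]]) / sum(aligned)
    cov <- sum(aligned) / m
    ev <- if (is.null(calibration)) NA_real_
          else evalue_of(calibration, m, n, h$score)
    structure(list(seq_id = record$id, profile_name = profile$name,
                   profile_label = profile$label, score = h$score,
                   score_bits = h$score / 2, evalue = ev,
                   percent_identity = ident, profile_coverage = cov,
                   seq_span = c(h$seq_start, h$seq_end),
                   profile_span = c(h$profile_start, h$profile_end),
                   path = data.frame(profile_col = pp, seq_pos = ps)),
              class = "profile_hit")
  })
  if (!is.null(calibration) && is.finite(max_evalue)) {
    hits <- Filter(function(h) h$evalue <= max_evalue, hits)
  }
  ord <- order(-vapply(hits, `[[`, 0, "score"),
               vapply(hits, function(h) h$seq_span[[1]], 0))
  hits[ord]
}

#' Percent identity against seed members
#'
#' Alternative identity reference for subfamily assignment: the maximum
#' global-alignment identity between the sequence and any stored seed
#' member of the profile (requires `keep_seeds = TRUE` at build time).
#'
#' @param profile a `kinase_profile` built with `keep_seeds = TRUE`.
#' @param record one row of a `seq_records` data.frame.
#' @param gap_open,gap_extend affine gap costs (see [pairwise_identity()]).
#' @return maximum percent identity, or `NA` if no seeds are stored.
#' @export
member_identity <- function(profile, record, gap_open = 11, gap_extend = 4) {
  if (is.null(profile$seeds)) return(NA_real_)
  max(vapply(profile$seeds$residues, function(s) {
    pairwise_identity(record$residues, s, gap_open, gap_extend)
  }, numeric(1)))
}

# -- pairwise identity -------------------------------------------------------

aa_substitution_matrix <- function(match = 5, mismatch = -4) {
  letters <- c(AA_STANDARD, "X")
  m <- matrix(mismatch, 21, 21, dimnames = list(letters, letters))
  diag(m) <- match
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

#' Global pairwise percent identity
#'
#' Needleman-Wunsch global alignment with affine gaps; identity is
#' 100 x (identical aligned pairs) / (aligned non-gap pairs).
#'
#' The default gap costs are deliberately stiffer than the profile
#' scanner's: with match +5 / mismatch -4, a gap extension of 4 makes
#' gapping out a mismatch run always costlier than aligning through it,
#' so unrelated sequences cannot inflate their identity by aligning only
#' chance matches.
#'
#' @param a,b amino-acid strings (or single rows of `seq_records`).
#' @param gap_open,gap_extend affine gap costs.
#' @return percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, gap_open = 11, gap_extend = 4) {
  if (is.list(a)) a <- a$residues
  if (is.list(b)) b <- b$residues
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = aa_substitution_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- pa != "-" & pb != "-"
  100 * sum(pa[both] == pb[both]) / sum(both)
}

# -- profile library serialization ------------------------------------------

#' Write a profile library to a directory
#'
#' One TSV score matrix per profile plus a YAML manifest holding names,
#' levels, labels, motif columns and calibration parameters.
#'
#' @param profiles a named list of `kinase_profile` objects.
#' @param dir output directory (created if needed).
#' @export
write_profile_library <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(profiles, function(p) {
    list(name = p$name, level = p$level, label = p$label,
         consensus = p$consensus, n_seeds = p$n_seeds,
         pseudocount_weight = p$pseudocount_weight,
         background = as.list(p$background),
         motif_columns = lapply(p$motif_columns, as.integer),
         catalytic_D_column = p$catalytic_D_column,
         calibration = if (!is.null(p$calibration))
           unclass(p$calibration))
  })
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (p in profiles) {
    write.table(p$scores, file.path(dir, paste0(p$name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a profile library written by [write_profile_library()]
#' @param dir library directory.
#' @return a named list of `kinase_profile` objects.
#' @export
read_profile_library <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  profiles <- lapply(manifest, function(m) {
    scores <- as.matrix(read.delim(file.path(dir, paste0(m$name, ".tsv"))))
    colnames(scores) <- AA_STANDARD
    cal <- if (!is.null(m$calibration)) {
      structure(m$calibration, class = "evalue_calibration")
    }
    motifs <- if (length(m$motif_columns)) {
      lapply(m$motif_columns, as.numeric)
    }
    structure(list(name = m$name, level = m$level, label = m$label,
                   scores = scores, consensus = m$consensus,
                   motif_columns = motifs,
                   catalytic_D_column = m$catalytic_D_column,
                   background = unlist(m$background)[AA_STANDARD],
                   n_seeds = m$n_seeds,
                   pseudocount_weight = m$pseudocount_weight,
                   seeds = NULL, calibration = cal),
              class = "kinase_profile")
  })
  names(profiles) <- vapply(profiles, `[[`, "", "name")
  profiles
}
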