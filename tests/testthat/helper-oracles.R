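# Independent oracles the tests compare the implementation against.

# Brute-force best local alignment score of a sequence against profile
# columns with affine gaps (open + extend for the first gapped position).
# Memoized recursion over (profile column, sequence position, state);
# written independently of the iterative scanner it checks.
brute_force_local_score <- function(scores, codes, gap_open, gap_extend) {
  L <- nrow(scores)
  n <- length(codes)
  memo <- array(NA_real_, c(L, n, 3))  # 1 = match, 2 = gap-in-seq, 3 = gap-in-profile
  rec <- function(i, j, s) {
    if (i < 1 || j < 1) return(-Inf)
    if (!is.na(memo[i, j, s])) return(memo[i, j, s])
    v <- if (s == 1) {
      scores[i, codes[j]] +
        max(0, rec(i - 1, j - 1, 1), rec(i - 1, j - 1, 2),
            rec(i - 1, j - 1, 3))
    } else if (s == 2) {
      max(rec(i - 1, j, 1) - gap_open - gap_extend,
          rec(i - 1, j, 2) - gap_extend)
    } else {
      max(rec(i, j - 1, 1) - gap_open - gap_extend,
          rec(i, j - 1, 3) - gap_extend)
    }
    memo[i, j, s] <<- v
    v
  }
  best <- -Inf
  for (i in seq_len(L)) {
    for (j in seq_len(n)) best <- max(best, rec(i, j, 1))
  }
  best
}

# Naive sliding-window hydropathy segments, written as explicit loops.
naive_tm_segments <- function(residues, window = 19, threshold = 1.6,
                              min_gap = 5) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  half <- (window - 1) / 2
  centers <- integer(0)
  for (c in (half + 1):(n - half)) {
    total <- 0
    for (k in (c - half):(c + half)) {
      total <- total + kinomescan::KYTE_DOOLITTLE[[chars[[k]]]]
    }
    if (total / window > threshold) centers <- c(centers, c)
  }
  if (length(centers) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  runs <- list(c(centers[[1]], centers[[1]]))
  for (c in centers[-1]) {
    last <- runs[[length(runs)]]
    if (c - last[[2]] - 1 < min_gap) {
      runs[[length(runs)]][2] <- c
    } else {
      runs[[length(runs) + 1]] <- c(c, c)
    }
  }
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = max(1, r[[1]] - half), end = min(n, r[[2]] + half))
  }))
}

random_aa_string <- function(n) {
  paste(sample(kinomescan::AA_STANDARD, n, replace = TRUE), collapse = "")
}
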