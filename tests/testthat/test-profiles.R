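test_that("pseudocount frequencies match the hand-computed formula", {
  # column 5 holds {A,A,A,G,G}; uniform background 0.05, weight 1
  set.seed(1)
  base <- random_aa_string(25)
  seqs <- vapply(c("A", "A", "A", "G", "G"), function(ch) {
    s <- base
    substr(s, 5, 5) <- ch
    s
  }, character(1))
  prof <- build_profile(alignment(seqs, paste0("s", 1:5)),
                        name = "hand", pseudocount_weight = 1)
  f_A <- (3 + 1 * 0.05) / (5 + 1)
  f_G <- (2 + 1 * 0.05) / (5 + 1)
  f_absent <- (0 + 1 * 0.05) / (5 + 1)
  expect_equal(unname(prof$scores[5, "A"]), 2 * log2(f_A / 0.05))
  expect_equal(unname(prof$scores[5, "G"]), 2 * log2(f_G / 0.05))
  expect_equal(unname(prof$scores[5, "W"]), 2 * log2(f_absent / 0.05))
})

test_that("a degenerate alignment of identical copies gives its own consensus", {
  set.seed(2)
  s <- random_aa_string(40)
  prof <- build_profile(alignment(rep(s, 5), paste0("s", 1:5)), name = "deg")
  expect_equal(prof$consensus, s)
  cons <- strsplit(s, "")[[1]]
  idx <- cbind(seq_len(40), match(cons, colnames(prof$scores)))
  expect_true(all(prof$scores[idx] > 0))
})

test_that("per-column expected score under the background is non-positive", {
  for (seed in 1:5) {
    set.seed(seed)
    seqs <- vapply(1:4, function(i) random_aa_string(30), character(1))
    prof <- build_profile(alignment(seqs, paste0("s", 1:4)),
                          name = "rnd")
    expected <- prof$scores %*% prof$background
    expect_true(all(expected <= 1e-12))
  }
})

test_that("gapped columns are dropped and motif columns remapped", {
  set.seed(3)
  base <- random_aa_string(30)
  seqs <- rep(base, 5)
  # column 12 gapped in 3 of 5 sequences (> 50%): dropped
  for (i in 1:3) substr(seqs[[i]], 12, 12) <- "-"
  prof <- build_profile(
    alignment(seqs, paste0("s", 1:5)), name = "gap",
    motif_columns = list(glycine_loop = c(10, 15)),
    catalytic_D_column = 20)
  expect_equal(nrow(prof$scores), 29)
  # independent index remap: kept columns are 1..11, 13..30
  kept <- setdiff(1:30, 12)
  remap <- match(intersect(10:15, kept), kept)
  expect_equal(prof$motif_columns$glycine_loop, range(remap))
  expect_equal(prof$catalytic_D_column, match(20, kept))
  expect_error(build_profile(alignment(c("--", "--")), name = "x"),
               "empty profile")
  expect_error(
    build_profile(structure(list(records = seq_records("a", "MK"),
                                 column_count = 2),
                            class = "aa_alignment"), name = "x"),
    "insufficient seed")
})

test_that("scanner score equals brute-force enumeration on small instances", {
  # the dynamic-programming scanner against a memoized-recursion oracle
  set.seed(99)
  for (case in 1:60) {
    L <- sample(5:30, 1)
    n <- sample(5:30, 1)
    nseq <- sample(2:4, 1)
    seqs <- vapply(seq_len(nseq), function(i) random_aa_string(L),
                   character(1))
    prof <- build_profile(alignment(seqs, paste0("s", seq_len(nseq))),
                          name = "bf")
    rec <- one_record("q", random_aa_string(n))
    go <- sample(c(3, 6, 11), 1)
    ge <- sample(c(0.5, 1, 2), 1)
    oracle <- brute_force_local_score(prof$scores,
                                      encode_residues(rec$residues),
                                      go, ge)
    hits <- scan_profile(prof, rec, gap_open = go, gap_extend = ge,
                         min_raw_score = 1e-9, max_hits = 1)
    if (oracle > 1e-9) {
      expect_equal(hits[[1]]$score, oracle, tolerance = 1e-10)
    } else {
      expect_length(hits, 0)
    }
  }
})

test_that("scanning the consensus yields full coverage and identity 100", {
  lib <- tiny_library()
  prof <- lib$subfamilies[[1]]
  rec <- one_record("cons", prof$consensus)
  hits <- scan_profile(prof, rec, max_evalue = 1e-4)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$profile_coverage, 1.0)
  expect_equal(hits[[1]]$percent_identity, 100)
  expect_equal(hits[[1]]$seq_span, c(1, nchar(rec$residues)))
})

test_that("an all-X sequence produces no hit", {
  lib <- tiny_library()
  rec <- one_record("xxx", strrep("X", 250))
  expect_length(scan_profile(lib$master, rec), 0)
})

test_that("scanning without a calibration or raw threshold is an error", {
  set.seed(4)
  prof <- build_profile(alignment(rep(random_aa_string(25), 2),
                                  c("a", "b")), name = "uncal")
  expect_error(scan_profile(prof, one_record("q", "MKLV")),
               "calibration missing")
})

test_that("calibration is deterministic and Gumbel moments behave", {
  lib <- tiny_library()
  prof <- lib$subfamilies[[1]]
  c1 <- calibrate_evalue(prof, decoy_length = 200, decoy_count = 200,
                         seed = 5)
  c2 <- calibrate_evalue(prof, decoy_length = 200, decoy_count = 200,
                         seed = 5)
  expect_identical(c1$lambda, c2$lambda)
  expect_identical(c1$K, c2$K)
  expect_true(c1$lambda > 0 && c1$K > 0)
  # shifting all scores by +c moves the location, not the scale
  set.seed(6)
  scores <- rnorm(500, 50, 5)
  f0 <- kinomescan:::gumbel_fit(scores)
  f1 <- kinomescan:::gumbel_fit(scores + 7)
  expect_equal(f1$lambda, f0$lambda)
  expect_equal(f1$mu, f0$mu + 7)
  expect_error(kinomescan:::gumbel_fit(rep(3, 300)),
               "calibration failure")
  expect_error(calibrate_evalue(prof, decoy_count = 100), ">= 200")
})

test_that("calibrated E-value of the best fresh decoy score is near 1 per database", {
  lib <- tiny_library()
  prof <- lib$subfamilies[[1]]
  cal <- calibrate_evalue(prof, decoy_length = 200, decoy_count = 300,
                          seed = 21)
  set.seed(22)
  n_fresh <- 200
  best <- vapply(seq_len(n_fresh), function(i) {
    rec <- one_record("d", random_aa_string(200))
    scan_profile(prof, rec, calibration = cal, max_evalue = Inf,
                 max_hits = 1)[[1]]$score
  }, numeric(1))
  e_top <- n_fresh * kinomescan:::evalue_of(cal, nrow(prof$scores), 200,
                                            max(best))
  expect_gt(e_top, 1 / 3)
  expect_lt(e_top, 3)
})

test_that("E-values decrease monotonically in score at fixed lengths", {
  lib <- tiny_library()
  cal <- lib$master$calibration
  s <- seq(20, 120, by = 10)
  e <- kinomescan:::evalue_of(cal, 200, 300, s)
  expect_true(all(diff(e) < 0))
})

test_that("pairwise identity matches direct cases and is symmetric", {
  expect_equal(pairwise_identity("MKLVGD", "MKLVGD"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  set.seed(8)
  for (i in 1:5) {
    a <- random_aa_string(sample(20:60, 1))
    b <- random_aa_string(sample(20:60, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})
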