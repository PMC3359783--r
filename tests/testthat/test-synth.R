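test_that("library generation is deterministic per seed", {
  a <- generate_library(group_count = 2, subfamilies_per_group = 1,
                        domain_length = 160, domain_labels = "SH2",
                        seed = 81)
  b <- generate_library(group_count = 2, subfamilies_per_group = 1,
                        domain_length = 160, domain_labels = "SH2",
                        seed = 81)
  c <- generate_library(group_count = 2, subfamilies_per_group = 1,
                        domain_length = 160, domain_labels = "SH2",
                        seed = 82)
  expect_identical(a$founders, b$founders)
  expect_identical(a$master$scores, b$master$scores)
  expect_false(identical(a$founders, c$founders))
})

test_that("the planted identity hierarchy orders within over between", {
  lib <- tiny_library()
  subs <- lib$subfamilies
  within <- mean(vapply(subs, function(p) {
    s <- p$seeds$residues
    mean(c(pairwise_identity(s[[1]], s[[2]]),
           pairwise_identity(s[[1]], s[[3]])))
  }, numeric(1)))
  groups <- names(lib$group_masters)
  between <- mean(c(
    pairwise_identity(lib$group_masters[[groups[[1]]]],
                      lib$group_masters[[groups[[2]]]]),
    pairwise_identity(lib$group_masters[[groups[[1]]]],
                      lib$group_masters[[groups[[3]]]])))
  expect_gt(within, between)
  # same-group subfamilies sit between the two extremes
  same_group <- pairwise_identity(lib$founders[[1]], lib$founders[[2]])
  expect_gt(within, same_group)
  expect_gt(same_group, between)
})

test_that("every seed sequence passes the motif cascade", {
  lib <- tiny_library()
  for (p in lib$subfamilies) {
    for (i in seq_len(nrow(p$seeds))) {
      rec <- p$seeds[i, ]
      hit <- scan_profile(lib$master, rec, max_evalue = 1e-4)[[1]]
      v <- apply_filter_cascade(rec, hit, lib$master)
      expect_true(v$accepted)
      expect_true(v$rd)
    }
  }
})

test_that("generated kinases sit at the planted divergence from their founder", {
  lib <- tiny_library()
  gen <- generate_proteome(lib, n_kinases = 50, n_decoys = 0,
                           divergence = 0.2, seed = 83)
  doms <- substr(gen$records$residues, 26, 25 + lib$domain_length)
  ident <- vapply(seq_len(50), function(i) {
    pairwise_identity(doms[[i]], lib$founders[[gen$truth$subfamily[[i]]]])
  }, numeric(1))
  expect_lt(abs(mean(ident) - 80), 5)
})

test_that("planted motif windows survive generation unmutated", {
  lib <- tiny_library()
  gen <- generate_proteome(lib, n_kinases = 30, n_decoys = 0,
                           divergence = 0.45, seed = 84)
  gly <- lib$motif_columns$glycine_loop
  cat <- lib$motif_columns$catalytic_loop
  for (i in seq_len(30)) {
    dom <- substr(gen$records$residues[[i]], 26, 25 + lib$domain_length)
    founder <- lib$founders[[gen$truth$subfamily[[i]]]]
    expect_equal(substr(dom, gly[[1]], gly[[2]]),
                 substr(founder, gly[[1]], gly[[2]]))
    expect_equal(substr(dom, cat[[1]], cat[[2]]),
                 substr(founder, cat[[1]], cat[[2]]))
  }
})

test_that("proteome generation is byte-identical per seed", {
  lib <- tiny_library()
  g1 <- generate_proteome(lib, n_kinases = 4, n_decoys = 4, n_pklnk = 2,
                          n_twin = 1, n_truncated = 1, n_receptor = 1,
                          seed = 85)
  g2 <- generate_proteome(lib, n_kinases = 4, n_decoys = 4, n_pklnk = 2,
                          n_twin = 1, n_truncated = 1, n_receptor = 1,
                          seed = 85)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(g1$records, f1)
  write_fasta(g2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$truth, g2$truth)
  expect_error(generate_proteome(lib, n_kinases = -1), "non-negative")
})

test_that("construct categories carry the intended structural features", {
  lib <- tiny_library()
  gen <- generate_proteome(lib, n_kinases = 2, n_decoys = 2, n_pklnk = 2,
                           n_twin = 1, n_truncated = 2, n_receptor = 1,
                           divergence = 0.1, seed = 86)
  tr <- gen$truth
  expect_true(all(nchar(gen$records$residues[tr$category ==
                                               "truncated"]) < 200))
  expect_true(all(nchar(gen$records$residues[tr$category ==
                                               "kinase"]) >= 200))
  d_col <- lib$catalytic_D_column
  pk <- gen$records$residues[tr$category == "pklnk"]
  expect_true(all(substr(pk, 25 + d_col, 25 + d_col) == "A"))
})

test_that("recovery metrics match a hand-built confusion case", {
  calls <- data.frame(
    seq_id = c("k1", "k2", "p1", "d1"),
    accepted = c(TRUE, FALSE, FALSE, TRUE),
    pklnk = c(FALSE, FALSE, TRUE, FALSE),
    group = c("AGC", NA, "TK", "STE"),
    subfamily = c("AGC_a", NA, "TK_a", "STE_a"),
    twin = FALSE, receptor = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(
    id = c("k1", "k2", "p1", "d1"),
    category = c("kinase", "kinase", "pklnk", "decoy"),
    group = c("AGC", "CMGC", "TK", NA),
    subfamily = c("AGC_a", "CMGC_a", "TK_a", NA),
    stringsAsFactors = FALSE)
  m <- recovery_metrics(calls, truth)
  expect_equal(m$sensitivity, 0.5)      # 1 of 2 kinases accepted
  expect_equal(m$precision, 0.5)        # 1 of 2 accepted is a kinase
  expect_equal(m$group_accuracy, 1)     # the accepted kinase is correct
  expect_equal(m$subfamily_accuracy, 1)
  expect_equal(m$pklnk_recall, 1)
  expect_equal(m$decoy_fpr, 1)          # the lone decoy was accepted
  expect_true(is.na(m$twin_recall))     # no twins planted

  all_reject <- calls
  all_reject$accepted <- FALSE
  expect_equal(recovery_metrics(all_reject, truth)$sensitivity, 0)
  expect_error(recovery_metrics(calls[1:3, ], truth), "id mismatch")
})
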