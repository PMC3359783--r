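fake_hit <- function(name, identity, coverage, score = 100,
                     seq_id = "q") {
  structure(list(seq_id = seq_id, profile_name = name,
                 profile_label = name, score = score,
                 score_bits = score / 2, evalue = 1e-10,
                 percent_identity = identity, profile_coverage = coverage,
                 seq_span = c(1, 100), profile_span = c(1, 100),
                 path = data.frame(profile_col = 1:100, seq_pos = 1:100)),
            class = "profile_hit")
}

test_that("identity exactly at the threshold is not classified (strict rule)", {
  lib <- tiny_library()
  sub <- names(lib$subfamilies)[[1]]
  asg <- assign_subfamily(NULL, list(fake_hit(sub, 30.0, 0.9)),
                          lib$manifest)
  expect_equal(asg$subfamily, "Unclassified")
  expect_equal(asg$group, "Other")
  # just above the threshold classifies; coverage threshold is non-strict
  asg2 <- assign_subfamily(NULL, list(fake_hit(sub, 30.01, 0.70)),
                          lib$manifest)
  expect_equal(asg2$subfamily, sub)
  expect_equal(asg2$group,
               lib$manifest$group[lib$manifest$name == sub])
  # coverage just below threshold fails
  asg3 <- assign_subfamily(NULL, list(fake_hit(sub, 80, 0.699)),
                           lib$manifest)
  expect_equal(asg3$subfamily, "Unclassified")
})

test_that("candidate tie-breaks follow identity, coverage, score, name", {
  lib <- tiny_library()
  subs <- names(lib$subfamilies)
  # equal identity: higher coverage wins
  asg <- assign_subfamily(NULL, list(fake_hit(subs[[1]], 50, 0.8),
                                     fake_hit(subs[[2]], 50, 0.9)),
                          lib$manifest)
  expect_equal(asg$subfamily, subs[[2]])
  # equal identity and coverage: higher score wins
  asg <- assign_subfamily(NULL,
                          list(fake_hit(subs[[1]], 50, 0.8, score = 90),
                               fake_hit(subs[[2]], 50, 0.8, score = 95)),
                          lib$manifest)
  expect_equal(asg$subfamily, subs[[2]])
  # full tie: lexicographically first profile name
  asg <- assign_subfamily(NULL,
                          list(fake_hit(subs[[2]], 50, 0.8),
                               fake_hit(subs[[1]], 50, 0.8)),
                          lib$manifest)
  expect_equal(asg$subfamily, sort(subs[1:2])[[1]])
})

test_that("subfamily assignment is invariant to hit order", {
  lib <- tiny_library()
  subs <- names(lib$subfamilies)
  hits <- list(fake_hit(subs[[1]], 45, 0.9), fake_hit(subs[[2]], 60, 0.8),
               fake_hit(subs[[3]], 55, 0.95))
  ref <- assign_subfamily(NULL, hits, lib$manifest)$subfamily
  set.seed(9)
  for (i in 1:5) {
    perm <- sample(hits)
    expect_equal(assign_subfamily(NULL, perm, lib$manifest)$subfamily, ref)
  }
})

test_that("hits naming unknown profiles raise a library-consistency error", {
  lib <- tiny_library()
  expect_error(assign_subfamily(NULL, list(fake_hit("nonesuch", 50, 0.9)),
                                lib$manifest),
               "library inconsistency")
})

test_that("census counts and percentages follow the half-up rounding rule", {
  calls <- data.frame(
    seq_id = paste0("s", 1:12),
    accepted = c(rep(TRUE, 10), FALSE, FALSE),
    pklnk = c(rep(FALSE, 10), TRUE, TRUE),
    group = c(rep("AGC", 2), rep("TK", 3), rep("Other", 5), "AGC", "TK"),
    subfamily = "x", rd = TRUE, stringsAsFactors = FALSE)
  tab <- census(calls, "toy", "group")
  expect_equal(tab$total, 10)  # PKLNKs are excluded from the denominator
  expect_equal(unname(tab$counts[c("AGC", "TK", "Other")]), c(2L, 3L, 5L))
  expect_equal(unname(tab$percentages[c("AGC", "TK", "Other")]),
               c(20, 30, 50))
  expect_lt(abs(sum(tab$percentages) - 100), 0.05)
  # order invariance
  set.seed(10)
  tab2 <- census(calls[sample(nrow(calls)), ], "toy", "group")
  expect_identical(tab, tab2)
})

test_that("percentages of any census sum to 100 within rounding slack", {
  lib <- tiny_library()
  gen <- generate_proteome(lib, n_kinases = 12, n_decoys = 4,
                           divergence = 0.2, seed = 23)
  calls <- classify_proteome(gen$records, lib, architecture = FALSE)
  for (level in c("group", "subfamily")) {
    tab <- census(calls, "synthA", level)
    expect_lt(abs(sum(tab$percentages) - 100), 0.05)
    expect_equal(sum(tab$counts), tab$total)
  }
})

test_that("over/under-representation flags compare the focal organism", {
  mk <- function(org, p) {
    structure(list(organism = org, level = "subfamily",
                   counts = setNames(rep(1L, length(p)), names(p)),
                   percentages = p, total = length(p)),
              class = "distribution_table")
  }
  t1 <- mk("fugu", c(DYRK = 5.0, CDK = 0.0, Eph = 2.0))
  t2 <- mk("human", c(DYRK = 1.0, CDK = 1.0, Eph = 2.0))
  t3 <- mk("worm", c(DYRK = 2.0, CDK = 2.0))        # Eph absent -> 0.00
  rep <- compare_distributions(list(t1, t2, t3), "fugu")
  expect_equal(rep$status[rep$label == "DYRK"], "over")
  expect_equal(rep$status[rep$label == "CDK"], "under")
  expect_equal(rep$status[rep$label == "Eph"], "none")  # human ties at 2.0
  expect_equal(rep$worm[rep$label == "Eph"], 0)
  expect_error(compare_distributions(list(t1), "fugu"), "length")
  t4 <- mk("human", c(DYRK = 1.0)); t4$level <- "group"
  expect_error(compare_distributions(list(t1, t4), "fugu"),
               "level mismatch")
})

test_that("classification is deterministic and rejects bad input", {
  lib <- tiny_library()
  gen <- generate_proteome(lib, n_kinases = 5, n_decoys = 3,
                           divergence = 0.15, seed = 31)
  c1 <- classify_proteome(gen$records, lib, architecture = FALSE)
  c2 <- classify_proteome(gen$records, lib, architecture = FALSE)
  expect_identical(c1, c2)
  expect_error(classify_proteome(gen$records[0, ], lib), "empty input")
})

test_that("a decoy-only proteome yields zero accepted calls", {
  lib <- tiny_library()
  gen <- generate_proteome(lib, n_kinases = 0, n_decoys = 12, seed = 37)
  calls <- classify_proteome(gen$records, lib, architecture = FALSE)
  expect_equal(sum(calls$accepted), 0)
})

test_that("planted kinases are recovered with their planted groups", {
  lib <- tiny_library()
  gen <- generate_proteome(lib, n_kinases = 10, n_decoys = 0,
                           divergence = 0.1, seed = 41)
  calls <- classify_proteome(gen$records, lib, architecture = FALSE)
  expect_equal(sum(calls$accepted), 10)
  expect_equal(calls$group, gen$truth$group)
  expect_equal(calls$subfamily, gen$truth$subfamily)
})
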