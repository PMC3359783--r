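# Synthetic proteomes, seed libraries and pathway fixtures with full
# ground truth.
#
# The generator plants a hierarchical identity structure: per group a
# random master domain sequence with a GXGXXG glycine-rich loop and an
# HRDLKxxN-style catalytic loop at fixed columns; subfamily founders
# derived from the group master at 30% substitution; per subfamily a
# 5-sequence seed alignment at 10% substitution.  Motif columns are never
# mutated (except where a construct deliberately removes the catalytic
# aspartate).  Substitutions are uniform over the 19 alternative residues,
# which keeps the identity-divergence arithmetic exact.

random_residues <- function(n, background = uniform_background()) {
  paste(sample(AA_STANDARD, n, replace = TRUE, prob = background),
        collapse = "")
}

# substitute each unprotected position with probability `divergence`,
# uniformly over the 19 alternative residues
mutate_residues <- function(residues, divergence, protect = integer(0)) {
  if (divergence == 0) return(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < divergence)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    chars[[i]] <- sample(setdiff(AA_STANDARD, chars[[i]]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic profile library
#'
#' Builds, deterministically per seed: one master domain sequence per
#' Hanks-Hunter group with planted glycine-rich loop (columns 9-14) and
#' catalytic loop (HRDLKxxN at the domain midpoint); subfamily founders at
#' `subfamily_divergence` substitution from the group master; 5-sequence
#' seed alignments per subfamily at `seed_divergence` substitution (motif
#' columns never mutated); a master kinase profile built from the group
#' masters; and decoy domain profiles for architecture analysis.
#'
#' @param group_count number of kinase groups (2-7; labels are the
#'   Hanks-Hunter names).
#' @param subfamilies_per_group subfamilies derived per group.
#' @param domain_length kinase domain length (>= 150).
#' @param seeds_per_subfamily sequences per seed alignment.
#' @param subfamily_divergence substitution rate group master -> subfamily
#'   founder.
#' @param seed_divergence substitution rate founder -> seed sequence.
#' @param domain_labels labels for the non-kinase co-occurring domain
#'   profiles.
#' @param accessory_domain_length length of the non-kinase domains.
#' @param seed RNG seed (the library is a pure function of it).
#' @return a list of class `profile_library` with `master`, `subfamilies`,
#'   `domains`, `manifest`, `founders`, `motif_columns` and parameters.
#' @export
generate_library <- function(group_count = 7, subfamilies_per_group = 2,
                             domain_length = 300, seeds_per_subfamily = 5,
                             subfamily_divergence = 0.30,
                             seed_divergence = 0.10,
                             domain_labels = c("SH2", "PH", "galectin",
                                               "YkyA", "CNH", "PBD",
                                               "C1_1", "DMPK_Coil"),
                             accessory_domain_length = 110, seed = 1) {
  stopifnot(domain_length >= 150, group_count >= 2, group_count <= 7,
            subfamilies_per_group >= 1, seeds_per_subfamily >= 2)
  groups <- HANKS_HUNTER_GROUPS[seq_len(group_count)]
  gly_cols <- 9:14
  cat_start <- floor(domain_length / 2)
  cat_cols <- seq(cat_start, cat_start + 7)
  d_col <- cat_start + 2
  protect <- c(gly_cols, cat_cols)

  with_seed(seed, {
    plant_motifs <- function(res) {
      chars <- strsplit(res, "", fixed = TRUE)[[1]]
      x <- function() sample(setdiff(AA_STANDARD, "G"), 1)
      chars[gly_cols] <- c("G", x(), "G", x(), x(), "G")
      chars[cat_cols] <- c("H", "R", "D", "L", "K", x(), x(), "N")
      paste(chars, collapse = "")
    }
    masters <- setNames(lapply(groups, function(g) {
      plant_motifs(random_residues(domain_length))
    }), groups)

    founders <- list()
    subfam_profiles <- list()
    manifest <- list()
    for (g in groups) {
      for (k in seq_len(subfamilies_per_group)) {
        sub <- paste0(g, "_", letters[[k]])
        founder <- mutate_residues(masters[[g]], subfamily_divergence,
                                   protect)
        founders[[sub]] <- founder
        seeds <- vapply(seq_len(seeds_per_subfamily), function(s) {
          mutate_residues(founder, seed_divergence, protect)
        }, character(1))
        aln <- alignment(seeds, paste0(sub, "_seed",
                                       seq_len(seeds_per_subfamily)))
        subfam_profiles[[sub]] <- build_profile(
          aln, name = sub, level = "subfamily", label = sub,
          motif_columns = list(glycine_loop = range(gly_cols),
                               catalytic_loop = range(cat_cols)),
          catalytic_D_column = d_col, keep_seeds = TRUE)
        manifest[[length(manifest) + 1]] <-
          data.frame(name = sub, level = "subfamily", label = sub,
                     group = g, stringsAsFactors = FALSE)
      }
    }

    master_aln <- alignment(unlist(masters), paste0("master_", groups))
    # the master profile must recognise members of every group: heavier
    # pseudocount regularisation (weight = seed count) keeps the penalty
    # for group-specific residues mild so that local alignments extend
    # across the whole domain instead of fragmenting
    master <- build_profile(
      master_aln, name = "kinase_master", level = "group",
      label = "kinase", pseudocount_weight = group_count,
      motif_columns = list(glycine_loop = range(gly_cols),
                           catalytic_loop = range(cat_cols)),
      catalytic_D_column = d_col)

    domain_founders <- list()
    domain_profiles <- list()
    for (lab in domain_labels) {
      founder <- random_residues(accessory_domain_length)
      domain_founders[[lab]] <- founder
      seeds <- vapply(1:5, function(s) mutate_residues(founder, 0.10),
                      character(1))
      aln <- alignment(seeds, paste0(lab, "_seed", 1:5))
      domain_profiles[[lab]] <- build_profile(aln, name = lab,
                                              level = "domain",
                                              label = lab)
      manifest[[length(manifest) + 1]] <-
        data.frame(name = lab, level = "domain", label = lab,
                   group = NA_character_, stringsAsFactors = FALSE)
    }

    structure(list(
      master = master, subfamilies = subfam_profiles,
      domains = domain_profiles,
      manifest = do.call(rbind, manifest),
      founders = founders, group_masters = masters,
      domain_founders = domain_founders,
      motif_columns = list(glycine_loop = range(gly_cols),
                           catalytic_loop = range(cat_cols)),
      catalytic_D_column = d_col, domain_length = domain_length,
      seed = seed), class = "profile_library")
  })
}

#' Calibrate every profile of a library
#'
#' @param library a `profile_library`.
#' @param decoy_length,decoy_count calibration decoys per profile.
#' @param seed base RNG seed; each profile gets a derived seed.
#' @return the library with all profiles calibrated.
#' @export
calibrate_library <- function(library, decoy_length = 350,
                              decoy_count = 200, seed = 101) {
  i <- 0
  cal <- function(p) {
    i <<- i + 1
    calibrate_profile(p, decoy_length = decoy_length,
                      decoy_count = decoy_count, seed = seed + i)
  }
  library$master <- cal(library$master)
  library$subfamilies <- lapply(library$subfamilies, cal)
  library$domains <- lapply(library$domains, cal)
  library
}

# positions of motif columns within a generated domain (identity layout)
library_protected_columns <- function(library) {
  c(seq(library$motif_columns$glycine_loop[[1]],
        library$motif_columns$glycine_loop[[2]]),
    seq(library$motif_columns$catalytic_loop[[1]],
        library$motif_columns$catalytic_loop[[2]]))
}

#' Generate a synthetic proteome with ground truth
#'
#' Kinases are drawn from random subfamilies at the stated divergence with
#' motif columns preserved; PKLNK variants carry a catalytic D->A
#' substitution; twins concatenate two same-subfamily domains with a
#' polar linker; truncated variants are cut below 200 residues (motifs
#' retained); receptor variants carry a 25-residue hydrophobic stretch
#' plus flanking sequence; decoys are i.i.d. background draws.
#' Deterministic per seed.
#'
#' @param library a `profile_library`.
#' @param n_kinases,n_decoys,n_pklnk,n_twin,n_truncated,n_receptor
#'   construct counts (all >= 0).
#' @param divergence substitution rate from the subfamily founder (0-0.5).
#' @param organism organism tag recorded in ids and truth.
#' @param seed RNG seed.
#' @return list with `records` (a `seq_records`) and `truth` (data.frame:
#'   `id`, `category`, `is_kinase`, `group`, `subfamily`, `pklnk`, `twin`,
#'   `n_tm`, `divergence`, `organism`).
#' @export
generate_proteome <- function(library, n_kinases = 20, n_decoys = 20,
                              n_pklnk = 0, n_twin = 0, n_truncated = 0,
                              n_receptor = 0, divergence = 0.25,
                              organism = "synthA", seed = 1) {
  counts <- c(n_kinases, n_decoys, n_pklnk, n_twin, n_truncated,
              n_receptor)
  if (any(counts < 0)) stop("construct counts must be non-negative")
  stopifnot(divergence >= 0, divergence <= 0.5)
  protect <- library_protected_columns(library)
  d_col <- library$catalytic_D_column
  subfams <- names(library$founders)
  manifest <- library$manifest
  group_of <- function(sub) {
    manifest$group[manifest$name == sub][[1]]
  }

  with_seed(seed, {
    recs <- list(); truth <- list()
    add <- function(id, res, category, group = NA, subfamily = NA,
                    pklnk = FALSE, twin = FALSE, n_tm = 0L,
                    is_kinase = FALSE) {
      recs[[length(recs) + 1]] <<- data.frame(
        id = id, description = category, residues = res,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <<- data.frame(
        id = id, category = category, is_kinase = is_kinase,
        group = group, subfamily = subfamily, pklnk = pklnk,
        twin = twin, n_tm = n_tm, divergence = divergence,
        organism = organism, stringsAsFactors = FALSE)
    }
    new_domain <- function(sub) {
      mutate_residues(library$founders[[sub]], divergence, protect)
    }
    flank <- function(n) random_residues(n)

    for (i in seq_len(n_kinases)) {
      sub <- sample(subfams, 1)
      add(sprintf("%s_kin%03d", organism, i),
          paste0(flank(25), new_domain(sub), flank(25)),
          "kinase", group_of(sub), sub, is_kinase = TRUE)
    }
    for (i in seq_len(n_pklnk)) {
      sub <- sample(subfams, 1)
      dom <- new_domain(sub)
      substr(dom, d_col, d_col) <- "A"
      add(sprintf("%s_pklnk%03d", organism, i),
          paste0(flank(25), dom, flank(25)),
          "pklnk", group_of(sub), sub, pklnk = TRUE)
    }
    for (i in seq_len(n_twin)) {
      sub <- sample(subfams, 1)
      linker <- paste(sample(c("G", "S", "T", "N", "Q", "D", "E", "K"),
                             25, replace = TRUE), collapse = "")
      add(sprintf("%s_twin%03d", organism, i),
          paste0(flank(20), new_domain(sub), linker, new_domain(sub),
                 flank(10)),
          "twin", group_of(sub), sub, twin = TRUE, is_kinase = TRUE)
    }
    for (i in seq_len(n_truncated)) {
      sub <- sample(subfams, 1)
      full <- paste0(flank(25), new_domain(sub))
      cut <- min(199, 25 + library$motif_columns$catalytic_loop[[2]] + 13,
                 nchar(full))
      add(sprintf("%s_trunc%03d", organism, i), substr(full, 1, cut),
          "truncated", group_of(sub), sub)
    }
    for (i in seq_len(n_receptor)) {
      sub <- sample(subfams, 1)
      tm <- paste(sample(c("L", "I", "V", "F"), 25, replace = TRUE),
                  collapse = "")
      add(sprintf("%s_rtk%03d", organism, i),
          paste0(flank(15), tm, flank(10), new_domain(sub), flank(20)),
          "receptor", group_of(sub), sub, n_tm = 1L, is_kinase = TRUE)
    }
    for (i in seq_len(n_decoys)) {
      add(sprintf("%s_decoy%03d", organism, i),
          random_residues(sample(250:450, 1)), "decoy")
    }
    records <- do.call(rbind, recs)
    class(records) <- c("seq_records", "data.frame")
    list(records = records, truth = do.call(rbind, truth))
  })
}

#' Generate two-organism cohorts for one subfamily
#'
#' Emulates an organism-specific expansion: the divergent organism's
#' members derive from an extra-divergent template of the subfamily
#' founder, the other organism's directly from the founder, so the
#' divergent cohort forms its own cluster in dendrograms.
#'
#' @param library a `profile_library`.
#' @param subfamily subfamily name (from the library manifest).
#' @param organisms two organism tags.
#' @param divergent_organism which of the two uses the divergent template.
#' @param n_per_organism members per organism.
#' @param divergence within-cohort substitution rate.
#' @param template_divergence founder -> divergent-template substitution
#'   rate.
#' @param seed RNG seed.
#' @return list with `records` (domain-only sequences) and
#'   `leaf_organisms` (named vector).
#' @export
generate_organism_cohorts <- function(library, subfamily,
                                      organisms = c("fugu", "human"),
                                      divergent_organism = organisms[[1]],
                                      n_per_organism = 8,
                                      divergence = 0.10,
                                      template_divergence = 0.40,
                                      seed = 1) {
  stopifnot(length(organisms) == 2, subfamily %in% names(library$founders))
  protect <- library_protected_columns(library)
  founder <- library$founders[[subfamily]]
  with_seed(seed, {
    divergent_template <- mutate_residues(founder, template_divergence,
                                          protect)
    rows <- list()
    for (org in organisms) {
      templ <- if (org == divergent_organism) divergent_template
               else founder
      for (i in seq_len(n_per_organism)) {
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("%s_%s_%02d", org, subfamily, i),
          description = org,
          residues = mutate_residues(templ, divergence, protect),
          stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    class(records) <- c("seq_records", "data.frame")
    list(records = records,
         leaf_organisms = setNames(records$description, records$id))
  })
}

#' Generate a pathway-mapping fixture
#'
#' Templates with planted presence classes in a synthetic target
#' proteome: `close` templates have a near-identical full-length
#' counterpart; `remote` templates a high-identity counterpart covering
#' only part of the template (significant hit, coverage below the close
#' threshold); `absent` templates no counterpart.
#'
#' @param n_close,n_remote,n_absent template counts per class.
#' @param template_length template length.
#' @param close_divergence substitution rate for close counterparts.
#' @param remote_fraction fraction of the template retained by remote
#'   counterparts (below the 0.70 coverage threshold).
#' @param n_extra_decoys unrelated proteome sequences.
#' @param seed RNG seed.
#' @return list with `templates`, `proteome` (both `seq_records`) and
#'   `truth` (data.frame `template_id`, `presence_class`).
#' @export
generate_pathway_fixture <- function(n_close = 15, n_remote = 3,
                                     n_absent = 2, template_length = 300,
                                     close_divergence = 0.02,
                                     remote_fraction = 0.55,
                                     n_extra_decoys = 5, seed = 1) {
  with_seed(seed, {
    tmpl <- list(); prot <- list(); truth <- list()
    add_t <- function(id, res, cls) {
      tmpl[[length(tmpl) + 1]] <<- data.frame(
        id = id, description = cls, residues = res,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <<- data.frame(
        template_id = id, presence_class = cls, stringsAsFactors = FALSE)
    }
    add_p <- function(id, res) {
      prot[[length(prot) + 1]] <<- data.frame(
        id = id, description = "", residues = res, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_close)) {
      res <- random_residues(template_length)
      add_t(sprintf("tmpl_close%02d", i), res, "close")
      add_p(sprintf("prot_close%02d", i), mutate_residues(res,
                                                          close_divergence))
    }
    for (i in seq_len(n_remote)) {
      res <- random_residues(template_length)
      add_t(sprintf("tmpl_remote%02d", i), res, "remote")
      frag <- substr(res, 1, round(remote_fraction * template_length))
      add_p(sprintf("prot_remote%02d", i),
            paste0(mutate_residues(frag, 0.05),
                   random_residues(60)))
    }
    for (i in seq_len(n_absent)) {
      add_t(sprintf("tmpl_absent%02d", i),
            random_residues(template_length), "absent")
    }
    for (i in seq_len(n_extra_decoys)) {
      add_p(sprintf("prot_decoy%02d", i),
            random_residues(sample(200:400, 1)))
    }
    templates <- do.call(rbind, tmpl)
    proteome <- do.call(rbind, prot)
    class(templates) <- class(proteome) <- c("seq_records", "data.frame")
    list(templates = templates, proteome = proteome,
         truth = do.call(rbind, truth))
  })
}

#' Score pipeline recovery against planted truth
#'
#' @param calls a call table from [classify_proteome()].
#' @param truth the `truth` data.frame from [generate_proteome()].
#' @return named list: `sensitivity`, `precision`, `group_accuracy`,
#'   `subfamily_accuracy`, `pklnk_recall`, `twin_recall`,
#'   `receptor_recall`, `truncated_rejection`, `decoy_fpr` (components
#'   with no eligible sequences are `NA`).
#' @export
recovery_metrics <- function(calls, truth) {
  if (!setequal(calls$seq_id, truth$id)) {
    stop("id mismatch between calls and truth")
  }
  truth <- truth[match(calls$seq_id, truth$id), ]
  functional <- truth$category %in% c("kinase", "twin", "receptor")
  rate <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  acc_fun <- calls$accepted & functional
  list(
    sensitivity = rate(calls$accepted[functional]),
    precision = if (sum(calls$accepted) == 0) NA_real_
                else sum(acc_fun) / sum(calls$accepted),
    group_accuracy = rate((calls$group == truth$group)[acc_fun]),
    subfamily_accuracy = rate((calls$subfamily == truth$subfamily)[acc_fun]),
    pklnk_recall = rate(calls$pklnk[truth$category == "pklnk"]),
    twin_recall = rate(calls$twin[truth$category == "twin"]),
    receptor_recall = rate(calls$receptor[truth$category == "receptor"]),
    truncated_rejection = rate(!calls$accepted[truth$category ==
                                                 "truncated"]),
    decoy_fpr = rate(calls$accepted[truth$category == "decoy"]))
}
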