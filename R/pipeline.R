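# End-to-end pipeline driver: library, calibration, classification,
# census, architectures, clustering, reports, with per-stage sequence
# counts logged the way the annotation protocol is audited.

#' Write a pipeline config as YAML
#' @param config a [default_config()] list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline config written by [write_config()]
#' @param path path to a YAML config.
#' @return a `pipeline_config` list (unknown fields rejected).
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the annotation pipeline end to end
#'
#' Generates (or accepts) a proteome and a calibrated profile library,
#' classifies every sequence, and writes the call table, filter report,
#' census tables, domain architectures, cluster report and per-stage
#' counts into `out_dir`.  All outputs are deterministic given the config
#' and seeds.
#'
#' @param config a [default_config()] list.
#' @param out_dir output directory (created).
#' @param proteome optional `seq_records`; by default a synthetic proteome
#'   is generated with `synth` (see `synth` argument).
#' @param library optional calibrated `profile_library`; generated and
#'   calibrated from `config$seed` when missing.
#' @param synth named list of [generate_proteome()] arguments used when
#'   `proteome` is missing.
#' @param organism organism tag for the census.
#' @param cluster if `TRUE` and at most `max_cluster_n` kinases are
#'   accepted, also cluster the catalytic domains and write a dendrogram.
#' @param max_cluster_n cap on the clustered set (pairwise alignments are
#'   quadratic).
#' @return invisibly, a list with `calls`, `census_group`, `stage_counts`,
#'   `truth` (when synthetic) and `metrics` (when synthetic).
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         proteome = NULL, library = NULL,
                         synth = list(n_kinases = 20, n_decoys = 10,
                                      n_pklnk = 3, n_truncated = 2),
                         organism = "synthA", cluster = TRUE,
                         max_cluster_n = 60) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  if (is.null(library)) {
    say("building synthetic profile library (seed %d)", config$seed)
    library <- generate_library(seed = config$seed)
    library <- calibrate_library(library, seed = config$seed + 1000)
  }
  if (is.null(library$master$calibration)) {
    stop("configuration error: library is not calibrated")
  }
  truth <- NULL
  if (is.null(proteome)) {
    gen <- do.call(generate_proteome,
                   c(list(library = library, organism = organism,
                          seed = config$seed), synth))
    proteome <- gen$records
    truth <- gen$truth
    write_fasta(proteome, file.path(out_dir, "proteome.fasta"))
    write_report(truth, file.path(out_dir, "truth.tsv"))
  }

  say("proteome: %d sequences", nrow(proteome))
  calls <- classify_proteome(proteome, library, config)
  stage_counts <- c(
    total = nrow(calls),
    profile_candidates = sum(calls$candidate),
    length_pass = sum(calls$candidate & calls$long_enough),
    glycine_pass = sum(calls$candidate & calls$long_enough &
                         calls$has_glycine_loop),
    accepted_kinases = sum(calls$accepted),
    pklnk = sum(calls$pklnk),
    rd_kinases = sum(calls$rd & calls$accepted),
    classified = sum(calls$accepted & calls$subfamily != "Unclassified"))
  for (nm in names(stage_counts)) say("stage %-20s %d", nm,
                                      stage_counts[[nm]])

  write_report(calls, file.path(out_dir, "calls.tsv"))
  cg <- census(calls, organism, "group")
  cs <- census(calls, organism, "subfamily")
  write_report(as.data.frame(cg), file.path(out_dir, "census_group.tsv"))
  write_report(as.data.frame(cs),
               file.path(out_dir, "census_subfamily.tsv"))

  arch_rows <- lapply(which(calls$accepted), function(i) {
    rec <- proteome[match(calls$seq_id[[i]], proteome$id), ]
    arch <- assign_domains(rec, c(list(kinase = library$master),
                                  library$domains),
                           evalue_cutoff = config$evalue_cutoff,
                           config = config)
    data.frame(seq_id = rec$id, architecture = format_architecture(arch),
               tm_segments = nrow(arch$tm_segments),
               stringsAsFactors = FALSE)
  })
  if (length(arch_rows)) {
    write_report(do.call(rbind, arch_rows),
                 file.path(out_dir, "architectures.tsv"))
  }

  if (cluster) {
    acc_ids <- calls$seq_id[calls$accepted]
    if (length(acc_ids) >= 3 && length(acc_ids) <= max_cluster_n) {
      doms <- catalytic_domain_records(
        proteome[match(acc_ids, proteome$id), ], library, config)
      d <- identity_distance_matrix(doms)
      writeLines(nj_tree(d), file.path(out_dir, "kinome.nwk"))
      part <- single_linkage_clusters(d, 0.7)
      say("single-linkage clusters at distance 0.7: %d", length(part))
    } else {
      say("clustering skipped (%d accepted kinases)", length(acc_ids))
    }
  }

  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- recovery_metrics(calls, truth)
    write_report(data.frame(metric = names(metrics),
                            value = unlist(metrics)),
                 file.path(out_dir, "recovery_metrics.tsv"))
  }

  write_config(config, file.path(out_dir, "config.yaml"))
  writeLines(log_lines, log_path)
  invisible(list(calls = calls, census_group = cg,
                 census_subfamily = cs, stage_counts = stage_counts,
                 truth = truth, metrics = metrics))
}
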