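# Identity-distance matrices, single-linkage clustering and
# neighbor-joining dendrograms.

#' Identity-based distance matrix
#'
#' Distance between two sequences is `(100 - percent identity) / 100`
#' under global affine-gap alignment.
#'
#' @param records a `seq_records` data.frame (>= 2 rows).
#' @param gap_open,gap_extend affine gap costs (see [pairwise_identity()]).
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
identity_distance_matrix <- function(records, gap_open = 11,
                                     gap_extend = 4) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records for a distance matrix")
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pid <- pairwise_identity(records$residues[[i]],
                               records$residues[[j]],
                               gap_open, gap_extend)
      d[i, j] <- d[j, i] <- (100 - pid) / 100
    }
  }
  d
}

#' Single-linkage clusters at a distance threshold
#'
#' Connected components of the graph joining pairs at distance <=
#' `distance_threshold`.  Singleton clusters are the outliers of the set.
#'
#' @param dist_matrix symmetric distance matrix with dimnames.
#' @param distance_threshold join pairs at or below this distance.
#' @return list of character vectors (label partition).
#' @export
single_linkage_clusters <- function(dist_matrix, distance_threshold) {
  stopifnot(isSymmetric(unname(dist_matrix)))
  adj <- dist_matrix <= distance_threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  split(rownames(dist_matrix), comp$membership)
}

#' Neighbor-joining dendrogram
#'
#' Standard neighbor joining on the distance matrix; negative branch
#' lengths are clamped to zero.  Returns the tree in Newick form.
#'
#' @param dist_matrix symmetric distance matrix (>= 3 labels) with
#'   dimnames.
#' @return a Newick string.
#' @export
nj_tree <- function(dist_matrix) {
  if (nrow(dist_matrix) < 3L) stop("neighbor joining needs >= 3 labels")
  tree <- ape::nj(as.dist(dist_matrix))
  if (any(tree$edge.length < 0)) {
    message("negative NJ branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  ape::write.tree(tree)
}

#' Detect organism-specific clusters
#'
#' Reports maximal clusters (tree clades, or partition members) of at
#' least `min_size` leaves in which at least a `purity` fraction of leaves
#' carry one organism tag.
#'
#' @param x a Newick string, an `ape` `phylo` tree, or a partition (list
#'   of character vectors) from [single_linkage_clusters()].
#' @param leaf_organisms named character vector: leaf label -> organism.
#' @param purity minimum fraction from the majority organism (default
#'   0.9).
#' @param min_size minimum cluster size (default 3).
#' @return list of clusters, each a list with `members`, `organism`,
#'   `purity`.
#' @export
detect_organism_specific_clusters <- function(x, leaf_organisms,
                                              purity = 0.9, min_size = 3) {
  clusters <- if (is.character(x) && length(x) == 1L) {
    tree_clades(ape::read.tree(text = x))
  } else if (inherits(x, "phylo")) {
    tree_clades(x)
  } else if (is.list(x)) {
    x
  } else stop("x must be a Newick string, a phylo tree, or a partition")
  leaves <- unique(unlist(clusters))
  missing <- setdiff(leaves, names(leaf_organisms))
  if (length(missing)) {
    stop("unlabeled leaves: ", paste(missing, collapse = ", "))
  }
  cand <- Filter(Negate(is.null), lapply(clusters, function(members) {
    if (length(members) < min_size) return(NULL)
    tab <- table(leaf_organisms[members])
    p <- max(tab) / length(members)
    if (p < purity) return(NULL)
    list(members = members, organism = names(tab)[[which.max(tab)]],
         purity = unname(p))
  }))
  # keep maximal clusters only
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (i != j && keep[j] &&
          all(cand[[i]]$members %in% cand[[j]]$members) &&
          length(cand[[i]]$members) < length(cand[[j]]$members)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cand[keep]
}

# all clades (leaf sets under each internal node) of a tree
tree_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  nodes <- (n_tip + 1):(n_tip + tree$Nnode)
  lapply(nodes, function(nd) {
    ape::extract.clade(tree, nd)$tip.label
  })
}

#' Extract catalytic-domain records
#'
#' Substrings covered by each sequence's best master-profile hit, for
#' domain-level clustering and dendrograms.
#'
#' @param records a `seq_records` proteome.
#' @param library a profile library with a calibrated `master`.
#' @param config pipeline config.
#' @return a `seq_records` data.frame of domain spans (sequences with no
#'   master hit are dropped).
#' @export
catalytic_domain_records <- function(records, library,
                                     config = default_config()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    hits <- scan_profile(library$master, rec, gap_open = config$gap_open,
                         gap_extend = config$gap_extend,
                         max_evalue = config$evalue_cutoff, max_hits = 1)
    if (length(hits) == 0L) return(NULL)
    sp <- hits[[1]]$seq_span
    data.frame(id = rec$id, description = rec$description,
               residues = substr(rec$residues, sp[[1]], sp[[2]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  class(out) <- c("seq_records", "data.frame")
  out
}
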