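#' Unrooted pairwise edge distances on a clone tree
#'
#' Breadth-first distances from `from` to every node, traversing edges in
#' both directions (path through common ancestors).
#'
#' @param tree a [clone_tree()].
#' @param from clone id.
#' @return named integer vector of edge counts to every node.
#' @keywords internal
node_distances <- function(tree, from) {
  check_clones_known(tree, from)
  adj <- tree_adjacency(tree)
  dist <- stats::setNames(rep(NA_integer_, length(tree$nodes)), tree$nodes)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

#' Clonal distance between two samples
#'
#' The number of tree edges required to traverse from a clone in one sample
#' to a clone in the other. For polyclonal samples the distance is the
#' minimum over all clone pairs; samples sharing a clone are at distance 0.
#'
#' @param tree a [clone_tree()].
#' @param clones_a,clones_b non-empty character vectors of clone ids.
#' @return non-negative integer edge count.
#' @export
clonal_distance <- function(tree, clones_a, clones_b) {
  if (length(clones_a) == 0 || length(clones_b) == 0) {
    ce_abort("both clone sets must be non-empty",
             class = "clonexpr_argument_error")
  }
  check_clones_known(tree, c(clones_a, clones_b))
  if (length(intersect(clones_a, clones_b)) > 0) return(0L)
  min(viapply(clones_a, function(a) {
    d <- node_distances(tree, a)
    min(d[clones_b])
  }))
}

#' Distance from a clone to the tumor MRCA
#'
#' Number of edges separating a clone from the root of its patient's clone
#' tree (the most recent common ancestor); 0 for the root itself.
#'
#' @param tree a [clone_tree()].
#' @param clone clone id.
#' @return non-negative integer depth.
#' @export
distance_to_mrca <- function(tree, clone) {
  check_clones_known(tree, clone)
  parent <- tree_parent_map(tree)
  d <- 0L; cur <- clone
  while (cur != tree$root) {
    cur <- parent[[cur]]
    d <- d + 1L
  }
  d
}

#' Terminal (leaf) clones of a tree
#'
#' Terminal clones are the leaves of the phylogeny; all other clones are
#' nonterminal (located internally).
#'
#' @param tree a [clone_tree()].
#' @return character vector of leaf clone ids.
#' @export
terminal_clones <- function(tree) {
  setdiff(tree$nodes, unique(tree$edges$parent))
}

#' Assign expression and TME profiles to individual clones
#'
#' Polyclonal tumor regions are excluded so each remaining region contains a
#' single clone. A clone observed in exactly one monoclonal region inherits
#' that region's expression/TME vectors; a clone observed in several gets the
#' arithmetic mean across those regions. Clones seen only in polyclonal
#' regions (or not at all) receive no profile and are reported.
#'
#' @param expr expression matrix (genes x samples); may be a score matrix
#'   (e.g. pathways x samples).
#' @param tme sample x population abundance matrix, or NULL.
#' @param metadata sample_meta table (tumor samples of one patient or a
#'   cohort; normal samples are ignored).
#' @param tree the patient's [clone_tree()]; only that patient's samples are
#'   used.
#' @return list of class `clone_profiles`: `expression` (genes x clones),
#'   `tme` (clones x populations or NULL), `info` (data.frame clone_id,
#'   n_source_regions, mean_purity), `unprofiled` (clone ids without
#'   profile).
#' @export
assign_clone_profiles <- function(expr, tme = NULL, metadata, tree) {
  sub <- metadata[metadata$patient_id == tree$patient_id &
                    metadata$sample_type != "normal", , drop = FALSE]
  n_clones <- viapply(sub$clones, length)
  mono <- sub[n_clones == 1L, , drop = FALSE]
  clone_of <- vcapply(mono$clones, identity)
  check_clones_known(tree, clone_of)
  profiled <- unique(clone_of)
  expr_prof <- NULL; tme_prof <- NULL; info <- list()
  for (cl in profiled) {
    ids <- mono$sample_id[clone_of == cl]
    e <- rowMeans(expr[, ids, drop = FALSE])
    expr_prof <- cbind(expr_prof, e)
    if (!is.null(tme)) {
      tme_prof <- rbind(tme_prof, colMeans(tme[ids, , drop = FALSE]))
    }
    info[[cl]] <- data.frame(clone_id = cl, n_source_regions = length(ids),
                             mean_purity = mean(mono$purity[clone_of == cl]),
                             stringsAsFactors = FALSE)
  }
  if (!is.null(expr_prof)) colnames(expr_prof) <- profiled
  if (!is.null(tme_prof)) rownames(tme_prof) <- profiled
  structure(list(expression = expr_prof, tme = tme_prof,
                 info = do.call(rbind, unname(info)) %||%
                   data.frame(clone_id = character(0),
                              n_source_regions = integer(0),
                              mean_purity = numeric(0)),
                 unprofiled = setdiff(tree$nodes, profiled)),
            class = "clone_profiles")
}

#' Classify a primary sample as seeding or nonseeding for a metastasis
#'
#' A primary tumor sample is "seeding" when it contains the clone that
#' spread to the matched metastasis (distance 0 from one of its clones to
#' the metastasis MRCA clone), and "nonseeding" otherwise. The reported
#' distance is the minimum edge distance from the sample's clones to the
#' metastasis MRCA clone (min rule for polyclonal primaries).
#'
#' @param tree the patient's [clone_tree()].
#' @param primary_sample_clones clones detected in the primary sample.
#' @param metastasis_mrca_clone the metastasis-founding clone (explicit
#'   annotation required).
#' @return list: `label` ("seeding"/"nonseeding"), `distance` (integer).
#' @export
classify_seeding <- function(tree, primary_sample_clones,
                             metastasis_mrca_clone) {
  check_clones_known(tree, metastasis_mrca_clone)
  d <- clonal_distance(tree, primary_sample_clones, metastasis_mrca_clone)
  list(label = if (d == 0L) "seeding" else "nonseeding", distance = d)
}

#' Within-patient clonal distance table
#'
#' Clonal distances for all within-patient sample pairs whose two samples
#' both have at least one detected clone; samples with zero detected clones
#' are excluded with a warning.
#'
#' @param metadata sample_meta table.
#' @param trees named list of clone trees keyed by patient id.
#' @param pair_types pair-type filter as in [pairwise_distances()].
#' @return data.frame: patient_id, sample_a, sample_b, pair_type,
#'   clonal_distance.
#' @export
clonal_distance_table <- function(metadata, trees,
                                  pair_types = "primary-primary") {
  tumor <- metadata[metadata$sample_type != "normal", , drop = FALSE]
  has_clone <- viapply(tumor$clones, length) > 0L
  if (any(!has_clone)) {
    ce_warn(sprintf("%d tumor sample(s) with no detected clones excluded from clonal distances",
                    sum(!has_clone)))
    tumor <- tumor[has_clone, , drop = FALSE]
  }
  rows <- list()
  for (pat in unique(tumor$patient_id)) {
    sub <- tumor[tumor$patient_id == pat, , drop = FALSE]
    tr <- trees[[pat]]
    ids <- sort(sub$sample_id)
    if (length(ids) < 2L || is.null(tr)) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        a <- ids[i]; b <- ids[j]
        ta <- sub$sample_type[sub$sample_id == a]
        tb <- sub$sample_type[sub$sample_id == b]
        ptype <- paste(sort(c(ta, tb)), collapse = "-")
        if (!ptype %in% pair_types) next
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pat, sample_a = a, sample_b = b, pair_type = ptype,
          clonal_distance = clonal_distance(tr,
                                            sub$clones[[which(sub$sample_id == a)]],
                                            sub$clones[[which(sub$sample_id == b)]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows) %||%
    data.frame(patient_id = character(0), sample_a = character(0),
               sample_b = character(0), pair_type = character(0),
               clonal_distance = integer(0))
}
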