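#' Construct a clone phylogeny
#'
#' A `clone_tree` is a rooted tree over clone identifiers: the root is the
#' most recent common ancestor (MRCA) of the tumor, edges point parent to
#' child, and each clone may carry a genotype (driver mutations, per-gene
#' copy number, chromosome-arm events).
#'
#' @param patient_id patient identifier.
#' @param edges data.frame with character columns `parent`, `child`; may have
#'   zero rows for a single-clone tree (then `nodes` must name the clone).
#' @param nodes optional character vector of clone ids; defaults to the union
#'   of edge endpoints.
#' @param genotypes named list, one entry per clone, each a list with
#'   optional elements `driver_mutations` (character), `cn` (named integer),
#'   `arm_events` (named character in {loss, neutral, gain}).
#' @return object of class `clone_tree`.
#' @export
clone_tree <- function(patient_id, edges, nodes = NULL, genotypes = list()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 &&
      !all(c("parent", "child") %in% names(edges))) {
    ce_abort("edges must have 'parent' and 'child' columns",
             class = "clonexpr_structure_error")
  }
  if (nrow(edges) == 0) {
    edges <- data.frame(parent = character(0), child = character(0),
                        stringsAsFactors = FALSE)
  }
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  nodes <- unique(c(nodes, edges$parent, edges$child))
  if (length(nodes) == 0) {
    ce_abort("clone tree needs at least one node",
             class = "clonexpr_structure_error")
  }
  if (anyDuplicated(edges$child)) {
    dup <- unique(edges$child[duplicated(edges$child)])
    ce_abort(sprintf("clone(s) with multiple parents: %s",
                     paste(dup, collapse = ", ")),
             class = "clonexpr_structure_error")
  }
  parentless <- setdiff(nodes, edges$child)
  if (length(parentless) != 1L) {
    ce_abort(sprintf("tree must have exactly one root; found %d parentless node(s): %s",
                     length(parentless), paste(parentless, collapse = ", ")),
             class = "clonexpr_structure_error")
  }
  root <- parentless
  # reachability check (connected + acyclic given unique parents)
  children <- split(edges$child, factor(edges$parent, levels = nodes))
  seen <- character(0); frontier <- root
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    frontier <- unlist(children[frontier], use.names = FALSE)
  }
  if (length(seen) != length(nodes)) {
    ce_abort("clone tree is not connected (cycle or orphan subtree)",
             class = "clonexpr_structure_error")
  }
  bad_geno <- setdiff(names(genotypes), nodes)
  if (length(bad_geno)) {
    ce_abort(sprintf("genotype(s) for unknown clone(s): %s",
                     paste(bad_geno, collapse = ", ")),
             class = "clonexpr_structure_error")
  }
  structure(list(patient_id = as.character(patient_id), nodes = nodes,
                 edges = edges, root = root, genotypes = genotypes),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> patient %s: %d clones, root '%s'\n",
              x$patient_id, length(x$nodes), x$root))
  invisible(x)
}

tree_parent_map <- function(tree) {
  stats::setNames(tree$edges$parent, tree$edges$child)
}

tree_adjacency <- function(tree) {
  adj <- stats::setNames(vector("list", length(tree$nodes)), tree$nodes)
  for (i in seq_len(nrow(tree$edges))) {
    p <- tree$edges$parent[i]; c <- tree$edges$child[i]
    adj[[p]] <- c(adj[[p]], c)
    adj[[c]] <- c(adj[[c]], p)
  }
  adj
}

check_clones_known <- function(tree, clones) {
  unknown <- setdiff(clones, tree$nodes)
  if (length(unknown)) {
    ce_abort(sprintf("clone(s) not in tree of patient %s: %s", tree$patient_id,
                     paste(unknown, collapse = ", ")),
             class = "clonexpr_lookup_error")
  }
  invisible(TRUE)
}

#' Read a clone phylogeny
#'
#' Newick input is parsed with ape; all internal nodes must be labelled,
#' since clones may sit internally on the tree. Edge-list JSON carries
#' `patient_id`, `edges` (array of `{parent, child}`), optional `nodes` and
#' `genotypes`.
#'
#' @param path file path.
#' @param format `"newick"` or `"edge-json"`.
#' @param patient_id patient id to attach when the format does not carry one.
#' @return a [clone_tree()].
#' @export
read_clone_tree <- function(path, format = c("newick", "edge-json"),
                            patient_id = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    ce_abort(sprintf("tree file not found: %s", path),
             class = "clonexpr_io_error")
  }
  if (format == "newick") {
    txt <- paste(trimws(readLines(path, warn = FALSE)), collapse = "")
    parse_newick_clone_tree(txt, patient_id)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    edges <- as.data.frame(obj$edges %||%
                             list(parent = character(0), child = character(0)),
                           stringsAsFactors = FALSE)
    genotypes <- lapply(obj$genotypes %||% list(), function(g) {
      list(driver_mutations = as.character(g$driver_mutations %||% character(0)),
           cn = if (length(g$cn)) {
             stats::setNames(as.integer(unlist(g$cn)), names(g$cn))
           } else stats::setNames(integer(0), character(0)),
           arm_events = if (length(g$arm_events)) {
             stats::setNames(as.character(unlist(g$arm_events)), names(g$arm_events))
           } else stats::setNames(character(0), character(0)))
    })
    clone_tree(obj$patient_id %||% patient_id, edges,
               nodes = as.character(obj$nodes %||% NULL),
               genotypes = genotypes)
  }
}

# Newick with labelled internal nodes -> clone_tree. ape collapses a
# root-with-single-child, so we parse via ape only for proper binary-ish
# trees and fall back to a small recursive parser otherwise.
parse_newick_clone_tree <- function(txt, patient_id) {
  txt <- sub(";\\s*$", "", txt)
  edges <- list()
  walk <- function(s) {
    # returns list(label, rest) and appends edges
    s <- trimws(s)
    if (startsWith(s, "(")) {
      depth <- 0L; i <- 1L; n <- nchar(s)
      repeat {
        ch <- substr(s, i, i)
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") depth <- depth - 1L
        if (depth == 0L) break
        i <- i + 1L
        if (i > n) ce_abort("unbalanced parentheses in newick",
                            class = "clonexpr_parse_error")
      }
      inner <- substr(s, 2L, i - 1L)
      label <- trimws(substr(s, i + 1L, n))
      label <- sub(":.*$", "", label)
      if (label == "") ce_abort("unlabelled internal node in newick clone tree",
                                class = "clonexpr_parse_error")
      # split children at top-level commas
      kids <- character(0); depth <- 0L; start <- 1L
      for (j in seq_len(nchar(inner))) {
        ch <- substr(inner, j, j)
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") depth <- depth - 1L
        if (ch == "," && depth == 0L) {
          kids <- c(kids, substr(inner, start, j - 1L)); start <- j + 1L
        }
      }
      kids <- c(kids, substr(inner, start, nchar(inner)))
      for (k in kids) {
        kl <- walk(k)
        edges[[length(edges) + 1L]] <<- c(parent = label, child = kl)
      }
      label
    } else {
      lab <- sub(":.*$", "", s)
      if (lab == "") ce_abort("empty tip label in newick",
                              class = "clonexpr_parse_error")
      lab
    }
  }
  root_label <- walk(txt)
  if (length(edges) == 0) {
    return(clone_tree(patient_id, data.frame(parent = character(0),
                                             child = character(0)),
                      nodes = root_label))
  }
  edf <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  clone_tree(patient_id, edf)
}

#' Write a clone phylogeny
#'
#' @param tree a [clone_tree()].
#' @param path output path.
#' @param format `"edge-json"` (lossless) or `"newick"` (topology + labels).
#' @return `path`, invisibly.
#' @export
write_clone_tree <- function(tree, path, format = c("edge-json", "newick")) {
  format <- match.arg(format)
  if (format == "edge-json") {
    # named atomic vectors must become lists so jsonlite keeps the names
    genos <- lapply(tree$genotypes, function(g)
      list(driver_mutations = g$driver_mutations,
           cn = as.list(g$cn), arm_events = as.list(g$arm_events)))
    obj <- list(patient_id = tree$patient_id, nodes = tree$nodes,
                edges = tree$edges, root = tree$root,
                genotypes = genos)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(paste0(newick_string(tree, tree$root), ";"), path)
  }
  invisible(path)
}

newick_string <- function(tree, node) {
  kids <- tree$edges$child[tree$edges$parent == node]
  if (length(kids) == 0) return(node)
  paste0("(", paste(vcapply(kids, function(k) newick_string(tree, k)),
                    collapse = ","), ")", node)
}
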