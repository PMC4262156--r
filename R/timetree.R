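## Rooted time-tree data model: a bifurcating ape::phylo plus node ages in
## Ma before present (tips at 0). Internal representation is node ages, not
## branch lengths; branch lengths are derived on output.

#' Construct a time tree from a phylo object and node ages
#'
#' A `timetree` wraps a rooted, bifurcating [ape::phylo] topology with a
#' vector of node ages in Ma before present. Tips are extant (age 0) and
#' every internal node must be strictly older than each of its children.
#' The topology is fixed after construction.
#'
#' @param phy a rooted, strictly bifurcating `phylo` object.
#' @param ages numeric vector of ages (Ma) for all `2n - 1` nodes in
#'   `phylo` numbering (tips `1..n`, then internal nodes). Tip entries must
#'   be 0.
#' @param check if `TRUE` (default), reject trees violating the strict
#'   parent-older-than-child ordering.
#' @return an object of class `timetree` with elements `phy`, `ages` and
#'   `labels` (internal-node labels, possibly `NA`).
#' @seealso [parse_newick()], [validate_order()], [mrca_node()]
#' @export
timetree <- function(phy, ages, check = TRUE) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("polytomies are not supported")
  n <- length(phy$tip.label)
  if (length(ages) != 2L * n - 1L) {
    stop("'ages' must have one entry per node (", 2L * n - 1L, ")")
  }
  if (any(abs(ages[seq_len(n)]) > 1e-9)) {
    stop("all tips must sit at age 0")
  }
  ages[seq_len(n)] <- 0
  labels <- phy$node.label
  if (is.null(labels)) labels <- rep(NA_character_, n - 1L)
  labels[!nzchar(labels)] <- NA_character_
  obj <- structure(
    list(phy = phy, ages = as.numeric(ages), labels = labels),
    class = "timetree"
  )
  if (check) {
    v <- validate_order(obj)
    if (nrow(v) > 0L) {
      stop("age ordering violated at node(s): ",
           paste(utils::head(v$parent, 3L), collapse = ", "),
           " (parent not strictly older than child)")
    }
  }
  obj
}

#' @export
print.timetree <- function(x, ...) {
  cat("Time tree:", n_tips(x), "tips,", n_internal(x), "internal nodes\n")
  cat("Root age:", format(root_age(x)), "Ma\n")
  lab <- x$labels[!is.na(x$labels)]
  if (length(lab)) cat("Labelled clades:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname timetree
#' @param x,tree a `timetree`.
#' @export
n_tips <- function(tree) length(tree$phy$tip.label)

#' @rdname timetree
#' @export
n_internal <- function(tree) tree$phy$Nnode

#' @rdname timetree
#' @export
root_node <- function(tree) n_tips(tree) + 1L

#' @rdname timetree
#' @export
root_age <- function(tree) tree$ages[root_node(tree)]

#' Internal node ages as a named vector
#'
#' @param tree a `timetree`.
#' @return numeric vector of internal-node ages named by node label where
#'   available, otherwise by phylo node number.
#' @export
node_ages <- function(tree) {
  n <- n_tips(tree)
  ids <- (n + 1L):(2L * n - 1L)
  ages <- tree$ages[ids]
  nm <- tree$labels
  nm[is.na(nm)] <- as.character(ids[is.na(nm)])
  stats::setNames(ages, nm)
}

#' Replace internal node ages
#'
#' Returns a copy of the tree with new internal node ages. Ordering is not
#' re-checked, so that deliberately invalid states can be constructed for
#' density evaluation (where they have zero prior mass).
#'
#' @param tree a `timetree`.
#' @param ages numeric vector of internal-node ages in phylo node order
#'   (root first).
#' @export
set_node_ages <- function(tree, ages) {
  n <- n_tips(tree)
  stopifnot(length(ages) == n_internal(tree))
  tree$ages[(n + 1L):(2L * n - 1L)] <- as.numeric(ages)
  tree
}

#' Parse a chronogram from Newick text
#'
#' Branch lengths are interpreted as durations in Ma; node ages are computed
#' so that all tips sit at age 0. Non-ultrametric input (tips not
#' contemporaneous within `tol`) is rejected with an error naming the
#' offending tip, as are unrooted trees and polytomies.
#'
#' @param text a Newick string, or `NULL` if `file` is given.
#' @param file path to a Newick file.
#' @param tol tip-age tolerance in Ma (default `1e-6`).
#' @return a [timetree].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL, tol = 1e-6) {
  phy <- if (is.null(text)) ape::read.tree(file = file)
         else ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  if (is.null(phy$edge.length)) stop("Newick input must carry branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("polytomies are not supported")
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth)
  ages <- h - depth
  n <- length(phy$tip.label)
  bad <- which(abs(ages[seq_len(n)]) > tol)
  if (length(bad)) {
    stop("tips not contemporaneous (non-ultrametric input): ",
         paste(phy$tip.label[bad], collapse = ", "))
  }
  ages[seq_len(n)] <- 0
  timetree(phy, ages)
}

#' Write a time tree as Newick
#'
#' Branch lengths are derived from node ages (parent age minus child age).
#'
#' @param tree a `timetree`.
#' @param file optional output path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  phy <- tree$phy
  phy$edge.length <- tree$ages[phy$edge[, 1L]] - tree$ages[phy$edge[, 2L]]
  if (is.null(file)) ape::write.tree(phy) else ape::write.tree(phy, file = file)
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree a `timetree`.
#' @param taxa character vector of tip names (non-empty, all present in the
#'   tree). A single taxon returns the tip itself.
#' @return node id in phylo numbering.
#' @export
mrca_node <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("'taxa' must be non-empty")
  idx <- match(taxa, tree$phy$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip name(s): ", paste(taxa[is.na(idx)], collapse = ", "))
  }
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree$phy, taxa)
}

#' Find an internal node by its clade label
#'
#' @param tree a `timetree`.
#' @param label an internal-node label.
#' @return node id in phylo numbering.
#' @export
node_by_label <- function(tree, label) {
  hit <- which(tree$labels == label)
  if (length(hit) != 1L) stop("no unique node labelled '", label, "'")
  n_tips(tree) + hit
}

#' Check the ancestor-older-than-descendant ordering
#'
#' @param tree a `timetree`.
#' @param tol ties and near-ties (parent - child <= tol) count as
#'   violations; default `1e-9` Ma.
#' @return a data frame with one row per violation: `parent`, `child` node
#'   ids and their ages. Zero rows means the ordering holds strictly
#'   everywhere.
#' @export
validate_order <- function(tree, tol = 1e-9) {
  edge <- tree$phy$edge
  pa <- tree$ages[edge[, 1L]]
  ca <- tree$ages[edge[, 2L]]
  bad <- which(pa - ca <= tol)
  data.frame(
    parent = edge[bad, 1L], child = edge[bad, 2L],
    parent_age = pa[bad], child_age = ca[bad]
  )
}

## internal: indexing of internal nodes 1..M (phylo id = n_tips + i) and the
## child/parent tables consumed by the C++ sampler
tree_structure <- function(tree) {
  n <- n_tips(tree)
  M <- n_internal(tree)
  edge <- tree$phy$edge
  parent <- integer(M)
  ch_int <- vector("list", M)
  ch_tip <- vector("list", M)
  for (i in seq_len(M)) {
    ch_int[[i]] <- integer(0)
    ch_tip[[i]] <- integer(0)
  }
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L] - n
    ch <- edge[e, 2L]
    if (ch > n) {
      parent[ch - n] <- p
      ch_int[[p]] <- c(ch_int[[p]], ch - n)
    } else {
      ch_tip[[p]] <- c(ch_tip[[p]], ch)
    }
  }
  list(parent = parent, ch_int = ch_int, ch_tip = ch_tip,
       root = root_node(tree) - n, M = M, n_tip = n)
}
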