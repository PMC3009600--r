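# Fixed rooted phylogeny with named branches ("lineages").
#
# Substitution rates are free per lineage, so no branch lengths are needed.
# A lineage is identified by the name of the branch's child node; internal
# nodes without labels are named n1, n2, ... in the order ape assigns them.

#' Build a lineage tree from a Newick string or an ape phylo object
#'
#' The returned object records the rooted topology, parent pointers, and a
#' topological ordering used by the sequence simulator and the inference
#' engine. Every non-root node names one lineage (the branch leading to it).
#'
#' @param x a Newick string (must describe a rooted tree) or an object of
#'   class `phylo`.
#' @return an object of class `lineage_tree` with elements `nodes` (node
#'   names, leaves first), `parent` (integer index, `NA` for the root),
#'   `is_leaf`, `root`, `order` (parents-before-children node ordering) and
#'   `lineages` (names of all non-root nodes).
#' @export
lineage_tree <- function(x) {
  if (is.character(x)) {
    x <- ape::read.tree(text = x)
  }
  stopifnot(inherits(x, "phylo"))
  if (!ape::is.rooted(x)) {
    stop("tree must be rooted: every lineage needs a unique parent branch")
  }
  n_tip <- length(x$tip.label)
  n_node <- x$Nnode
  node_names <- character(n_tip + n_node)
  node_names[seq_len(n_tip)] <- x$tip.label
  if (!is.null(x$node.label) && all(nzchar(x$node.label))) {
    node_names[n_tip + seq_len(n_node)] <- x$node.label
  } else {
    node_names[n_tip + seq_len(n_node)] <- paste0("n", seq_len(n_node))
  }
  if (anyDuplicated(node_names)) stop("node names must be unique")
  parent <- rep(NA_integer_, n_tip + n_node)
  parent[x$edge[, 2L]] <- x$edge[, 1L]
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have a single root")
  ord <- integer(0)
  frontier <- root
  while (length(frontier)) {
    ord <- c(ord, frontier)
    frontier <- x$edge[x$edge[, 1L] %in% frontier, 2L]
  }
  structure(
    list(
      nodes = node_names,
      parent = parent,
      is_leaf = seq_along(node_names) <= n_tip,
      root = root,
      order = ord,
      lineages = node_names[-root],
      phylo = x
    ),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("lineage_tree:", sum(x$is_leaf), "leaves,",
      length(x$nodes) - sum(x$is_leaf), "internal nodes\n")
  cat("lineages:", paste(x$lineages, collapse = ", "), "\n")
  invisible(x)
}

#' Five-taxon sensu-stricto-like default topology
#'
#' A ladder topology mirroring the Saccharomyces sensu stricto clade used
#' throughout the analyses: `((((Scer,Spar)n1,Smik)n2,Skud)n3,Sbay)root`.
#' @return a `lineage_tree`.
#' @export
sensu_stricto_tree <- function() {
  lineage_tree("((((Scer,Spar)n1,Smik)n2,Skud)n3,Sbay)root;")
}

tree_children <- function(tree, node) which(tree$parent == node)

node_index <- function(tree, name) {
  i <- match(name, tree$nodes)
  if (is.na(i)) stop("unknown node: ", name)
  i
}
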