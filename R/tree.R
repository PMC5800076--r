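# Tree input/output and metrics.
#
# Trees are represented as ape "phylo" objects, rooted as given; the package
# never re-roots. Branch values (phylo$edge.length) are either expected
# substitutions per site (time-trees) or dimensionless dN/dS estimates
# (omega-trees), depending on context.

#' Parse a rooted newick tree
#'
#' Reads a newick string (or a file containing one) into an `ape::phylo`
#' object and validates it: exactly one root, unique non-empty tip labels,
#' branch lengths present and non-negative. Polytomies are accepted.
#'
#' @param text A newick string, or the path of a file holding one.
#' @return A rooted `phylo` object with `edge.length`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' patristic_distances(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    # locate the first structurally offending character for the error message
    bal <- cumsum((strsplit(text, "")[[1]] == "(") -
                    (strsplit(text, "")[[1]] == ")"))
    pos <- if (any(bal < 0)) which(bal < 0)[1] else nchar(text)
    stop("malformed newick string near position ", pos, call. = FALSE)
  }
  validate_tree(tr)
  tr
}

#' Serialize a tree to newick
#'
#' @param tree A valid `phylo` object (see [parse_newick()]).
#' @param digits Significant digits used for branch values.
#' @return A newick string terminated by ";".
#' @export
write_newick <- function(tree, digits = 12) {
  validate_tree(tree)
  ape::write.tree(tree, digits = digits)
}

#' Validate a tree object
#'
#' Checks the invariants assumed throughout the package: a single root,
#' every non-root node with exactly one parent, unique non-empty tip labels,
#' and non-negative branch values on all edges.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  lab <- tree$tip.label
  if (any(!nzchar(lab))) stop("empty tip labels", call. = FALSE)
  if (anyDuplicated(lab)) {
    stop("duplicate tip labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("negative or non-finite branch length", call. = FALSE)
  }
  nnode <- ape::Ntip(tree) + tree$Nnode
  parents <- tabulate(tree$edge[, 2], nbins = nnode)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1L) stop("tree must have exactly one root", call. = FALSE)
  if (any(parents > 1L)) stop("node with more than one parent", call. = FALSE)
  invisible(tree)
}

#' Patristic distances between tips
#'
#' Sum of branch values along the path connecting each pair of tips. On a
#' time-tree this is the usual patristic distance; on an omega-tree it is the
#' omega path length used e.g. as the inverse-distance weighting for Moran's I.
#'
#' @param tree A valid `phylo` object.
#' @return A symmetric tip-by-tip numeric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

# ---- internal structural helpers ------------------------------------------

tree_root <- function(tree) setdiff(tree$edge[, 1], tree$edge[, 2])[1]

# edge indices ordered so that children are visited before their parents
postorder_edges <- function(tree) ape::reorder.phylo(tree, "postorder")

# root-to-node path sum of branch values for every node (tips + internal)
node_depths <- function(tree) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(nnode)
  tr <- ape::reorder.phylo(tree, "cladewise") # parents before children
  for (i in seq_len(nrow(tr$edge))) {
    depth[tr$edge[i, 2]] <- depth[tr$edge[i, 1]] + tr$edge.length[i]
  }
  depth
}

# list of edge indices (into tree$edge) on the root-to-node path, per node
node_paths <- function(tree) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  paths <- vector("list", nnode)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ord <- attr(tr, "index_in_original") # may be NULL; map by matching edges
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    paths[[ch]] <- c(paths[[p]], i)
  }
  attr(paths, "edge") <- tr$edge
  attr(paths, "edge.length") <- tr$edge.length
  paths
}
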