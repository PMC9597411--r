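#' Read a rooted species tree
#'
#' Reads a newick tree with [ape::read.tree()] and validates it for use with
#' the loss models: rooted, binary, branch lengths present. A root edge
#' (a trailing branch length on the outermost clade, e.g. `(...):0.3;`) is the
#' branch between the hexaploidy event and the first speciation; if absent it
#' is set to 0 (it can be estimated during fitting).
#'
#' @param path Path to a newick file.
#' @param lengths_required If `TRUE` (default), missing branch lengths are an
#'   error; set `FALSE` when lengths will be fitted.
#' @return An [ape::phylo] object with a `root.edge` component.
#' @export
read_tree <- function(path, lengths_required = TRUE) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree in ", path)
  validate_tree(tr, lengths_required = lengths_required)
}

#' Write a species tree to newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a species tree against the model's requirements
#'
#' @param tree An [ape::phylo] object.
#' @param genomes Optional character vector; if given, the tree's leaf set
#'   must equal it exactly.
#' @param lengths_required If `TRUE`, branch lengths must be present and
#'   non-negative.
#' @return The tree, invisibly (with `root.edge` defaulted to 0).
#' @export
validate_tree <- function(tree, genomes = NULL, lengths_required = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted (resolve or re-root before use)")
  }
  if (length(tree$tip.label) > 2 && !ape::is.binary(tree)) {
    stop("tree must be binary; resolve multifurcations first")
  }
  if (lengths_required && is.null(tree$edge.length)) {
    stop("tree has no branch lengths; pass lengths_required = FALSE if they ",
         "will be fitted")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed (u = alpha*t >= 0)")
  }
  if (is.null(tree$root.edge)) tree$root.edge <- 0
  if (tree$root.edge < 0) stop("negative root edge")
  if (!is.null(genomes)) {
    if (!setequal(tree$tip.label, genomes) ||
        length(tree$tip.label) != length(genomes)) {
      stop("tree leaves {", paste(tree$tip.label, collapse = ", "),
           "} do not match the genome set {",
           paste(genomes, collapse = ", "), "}")
    }
  }
  invisible(tree)
}

# Compile a phylo into the postorder program consumed by the C++ pruning
# kernel. Returns leaf_seq (genome order of the state-index digits), the ops
# matrix, the edge lengths in edge-row order and the root edge length.
tree_plan <- function(tree) {
  tree <- validate_tree(tree, lengths_required = FALSE)
  n <- length(tree$tip.label)
  edges <- tree$edge
  lens <- tree$edge.length
  if (is.null(lens)) lens <- rep(NA_real_, nrow(edges))
  root <- n + 1L
  ops <- matrix(0L, nrow = 0, ncol = 3)
  leaf_seq <- character(0)
  build <- function(node) {
    rows <- which(edges[, 1] == node)
    if (length(rows) == 0) {
      erow <- which(edges[, 2] == node)
      leaf_seq <<- c(leaf_seq, tree$tip.label[node])
      ops <<- rbind(ops, c(1L, length(leaf_seq) - 1L, erow - 1L))
    } else {
      if (node != root && length(rows) != 2) stop("non-binary node in tree")
      for (r in rows) build(edges[r, 2])
      if (length(rows) == 2) {
        erow <- if (node == root) -1L else which(edges[, 2] == node) - 1L
        ops <<- rbind(ops, c(0L, 0L, as.integer(erow)))
      }
      # a root with a single child (degenerate 1-tip tree) needs no merge op;
      # its child edge is the only branch
    }
  }
  build(root)
  list(leaf_seq = leaf_seq, ops = ops, edge_lengths = lens,
       root_edge = tree$root.edge, n_edges = nrow(edges), tree = tree)
}

# Total branch count including the root edge
n_branches <- function(tree) {
  tree <- validate_tree(tree, lengths_required = FALSE)
  nrow(tree$edge) + 1L
}

# Replace branch lengths (root edge first, then edge rows) from a vector
set_branch_lengths <- function(tree, u) {
  stopifnot(length(u) == nrow(tree$edge) + 1L)
  tree$root.edge <- u[1]
  tree$edge.length <- u[-1]
  tree
}

# Model-implied state distribution at each tip (root-to-tip propagation),
# averaged; used to rank subgenomes by survival for canonical labelling.
model_tip_survival <- function(model, tree) {
  plan <- tree_plan(tree)
  edges <- plan$tree$edge
  n <- length(plan$tree$tip.label)
  rd <- root_distribution(model)
  Proot <- transition_matrix(model, plan$root_edge, branch = "root")
  at_root <- as.numeric(rd %*% Proot)
  dist <- matrix(0, nrow = n + plan$tree$Nnode, ncol = 7)
  dist[n + 1L, ] <- at_root
  prop <- function(node) {
    rows <- which(edges[, 1] == node)
    for (r in rows) {
      child <- edges[r, 2]
      P <- transition_matrix(model, plan$edge_lengths[r])
      dist[child, ] <<- as.numeric(dist[node, ] %*% P)
      if (child > n) prop(child)
    }
  }
  prop(n + 1L)
  surv <- t(apply(dist[seq_len(n), , drop = FALSE], 1, subgenome_survival))
  rownames(surv) <- plan$tree$tip.label
  surv
}
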