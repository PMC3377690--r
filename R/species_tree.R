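#' Construct a validated species tree
#'
#' Wraps an \code{ape} \code{phylo} object after checking that it is rooted,
#' strictly binary, fully named with unique node names, carries branch
#' lengths (interpreted as million years), and is ultrametric: every leaf
#' must sit at the same depth below the root within \code{tol} times the
#' root depth.  The tree is the fixed coordinate system for every event the
#' pipeline reports; a non-ultrametric tree is rejected rather than
#' normalised because the divergence-time calibration used by the
#' protein-level conservation test is meaningless otherwise.
#'
#' @param phy an \code{ape::phylo} object.
#' @param tol relative ultrametricity tolerance.
#' @return an object of class \code{species_tree}.
#' @export
species_tree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("expected an ape phylo object")
  if (is.null(phy$edge.length)) stop("species tree must have branch lengths")
  if (anyNA(phy$edge.length)) stop("missing branch length in species tree")
  if (!ape::is.rooted(phy))
    stop("species tree must be rooted and binary (is the root a polytomy?)")
  if (!ape::is.binary(phy))
    stop("species tree must be strictly binary (polytomy found)")
  n_tip <- length(phy$tip.label)
  if (is.null(phy$node.label) || any(!nzchar(phy$node.label)))
    stop("all internal nodes of the species tree must be named")
  nm <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(nm))
    stop("duplicate node name in species tree: ", nm[duplicated(nm)][1L])
  # depths: distance from root to each node
  root <- n_tip + 1L
  nn <- n_tip + phy$Nnode
  parent <- integer(nn); parent[root] <- NA_integer_
  blen <- rep(NA_real_, nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  blen[phy$edge[, 2L]] <- phy$edge.length
  dist_root <- rep(NA_real_, nn)
  dist_root[root] <- 0
  # edges in preorder: ape edge matrix from root works if we iterate until fixed
  ord <- reorder_edges_preorder(phy)
  for (k in ord) {
    e <- phy$edge[k, ]
    dist_root[e[2L]] <- dist_root[e[1L]] + phy$edge.length[k]
  }
  depth <- stats::median(dist_root[seq_len(n_tip)])
  dev <- abs(dist_root[seq_len(n_tip)] - depth)
  if (any(dev > tol * max(depth, 1))) {
    off <- phy$tip.label[which.max(dev)]
    stop("species tree is not ultrametric: leaf ", off,
         " deviates by ", format(max(dev)), " MY from root depth ",
         format(depth))
  }
  # height above present of every node (0 at leaves)
  height <- depth - dist_root
  height[seq_len(n_tip)] <- 0
  structure(list(phylo = phy, names = nm, n_tip = n_tip,
                 parent = parent, blen = blen, height = height,
                 depth = depth, tol = tol),
            class = "species_tree")
}

reorder_edges_preorder <- function(phy) {
  # order edge rows so parents are visited before children
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  out <- integer(0)
  stack <- as.character(root)
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    ks <- kids[[nd]]
    if (!is.null(ks)) {
      out <- c(out, ks)
      stack <- c(stack, as.character(phy$edge[ks, 2L]))
    }
  }
  out
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree:", x$n_tip, "species, root depth", x$depth, "MY\n")
  cat("Species:", paste(x$phylo$tip.label, collapse = " "), "\n")
  invisible(x)
}

node_number <- function(tree, name) {
  i <- match(name, tree$names)
  if (anyNA(i)) stop("unknown node name: ",
                     paste(name[is.na(i)], collapse = ", "))
  i
}

node_name <- function(tree, num) tree$names[num]

ancestors_of <- function(tree, num) {
  # node numbers from num up to the root, inclusive
  out <- num
  while (!is.na(tree$parent[num])) {
    num <- tree$parent[num]
    out <- c(out, num)
  }
  out
}

#' Last common ancestor of a set of named nodes
#' @param tree a \code{species_tree}.
#' @param names character vector of leaf or internal node names.
#' @return the name of the lowest node ancestral to (or equal to) all inputs.
#' @export
tree_lca <- function(tree, names) {
  nums <- node_number(tree, unique(names))
  if (length(nums) == 1L) return(node_name(tree, nums))
  anc <- ancestors_of(tree, nums[1L])
  for (k in nums[-1L]) {
    a <- ancestors_of(tree, k)
    anc <- anc[anc %in% a]
  }
  node_name(tree, anc[1L])
}

#' Divergence time between two species
#'
#' The age in million years of the last common ancestor of two leaves,
#' measured from the present; well defined because the tree is ultrametric.
#' @param tree a \code{species_tree}.
#' @param a,b distinct leaf names.
#' @export
divergence_time <- function(tree, a, b) {
  if (identical(a, b)) stop("divergence time requires two distinct species")
  na_ <- node_number(tree, a); nb <- node_number(tree, b)
  if (na_ > tree$n_tip || nb > tree$n_tip)
    stop("divergence_time is defined between leaves")
  lca <- tree_lca(tree, c(a, b))
  tree$height[node_number(tree, lca)]
}

#' Species descending from an ancestor
#' @param tree a \code{species_tree}.
#' @param ancestor node name (leaf or internal).
#' @return character vector of leaf names in the subtree.
#' @export
species_under <- function(tree, ancestor) {
  num <- node_number(tree, ancestor)
  if (num <= tree$n_tip) return(tree$names[num])
  kids <- split(tree$phylo$edge[, 2L], tree$phylo$edge[, 1L])
  out <- integer(0)
  stack <- num
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (nd <= tree$n_tip) out <- c(out, nd)
    else stack <- c(stack, kids[[as.character(nd)]])
  }
  sort(tree$names[out])
}

#' Branches on the path from an ancestor down to a descendant
#'
#' Branches are identified by the name of their child node; the list runs in
#' root-to-leaf order.  \code{branch_path(x, x)} is empty.
#' @param tree a \code{species_tree}.
#' @param ancestor,descendant node names with \code{descendant} inside the
#'   subtree of \code{ancestor}.
#' @export
branch_path <- function(tree, ancestor, descendant) {
  na_ <- node_number(tree, ancestor); nd <- node_number(tree, descendant)
  chain <- ancestors_of(tree, nd)
  i <- match(na_, chain)
  if (is.na(i)) stop(descendant, " is not a descendant of ", ancestor)
  if (i == 1L) return(character(0))
  rev(tree$names[chain[seq_len(i - 1L)]])
}

#' Parent node name of a named node (NA for the root)
#' @param tree a \code{species_tree}.
#' @param name node name.
#' @export
parent_name <- function(tree, name) {
  p <- tree$parent[node_number(tree, name)]
  if (is.na(p)) NA_character_ else tree$names[p]
}

children_names <- function(tree, name) {
  num <- node_number(tree, name)
  kids <- tree$phylo$edge[tree$phylo$edge[, 1L] == num, 2L]
  tree$names[kids]
}

is_leaf <- function(tree, name) node_number(tree, name) <= tree$n_tip

#' Prune a species tree to a subset of species
#' @param tree a \code{species_tree}.
#' @param species leaf names to keep (at least 2).
#' @return a \code{species_tree} on the subset; internal names are retained.
#' @export
prune_species_tree <- function(tree, species) {
  stopifnot(length(species) >= 2L)
  phy <- ape::keep.tip(tree$phylo, species)
  species_tree(phy, tol = tree$tol)
}
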