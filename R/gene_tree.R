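#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with the Q criterion.  When several
#' pairs share the minimal Q value the lexicographically smallest label pair
#' is joined, which makes the output deterministic regardless of input
#' order.
#'
#' @param d symmetric distance matrix with labelled dimnames (>= 3 taxa).
#' @return an unrooted \code{ape::phylo} tree.
#' @export
build_nj <- function(d) {
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3L) stop("need at least 3 taxa")
  # active nodes represented as newick fragments
  frag <- labels
  act <- seq_len(n)
  dm <- d
  while (length(act) > 3L) {
    m <- length(act)
    rs <- rowSums(dm)
    best <- NULL; bestq <- Inf; bestkey <- NULL
    for (i in seq_len(m - 1L))
      for (j in seq(i + 1L, m)) {
        q <- (m - 2) * dm[i, j] - rs[i] - rs[j]
        key <- paste(sort(c(frag[act[i]], frag[act[j]])), collapse = "\r")
        if (q < bestq - 1e-12 ||
            (abs(q - bestq) <= 1e-12 && !is.null(bestkey) && key < bestkey)) {
          bestq <- q; best <- c(i, j); bestkey <- key
        }
      }
    i <- best[1L]; j <- best[2L]
    li <- dm[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- dm[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[act[i]], li,
                       frag[act[j]], lj)
    dnew <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    dm2 <- matrix(0, length(keep) + 1L, length(keep) + 1L)
    dm2[seq_along(keep), seq_along(keep)] <- dm[keep, keep, drop = FALSE]
    dm2[length(keep) + 1L, seq_along(keep)] <- dnew[keep]
    dm2[seq_along(keep), length(keep) + 1L] <- dnew[keep]
    frag <- c(frag, newfrag)
    act <- c(act[keep], length(frag))
    dm <- dm2
  }
  # final three-way join
  la <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  lb <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  lc <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[act[1L]], max(la, 0), frag[act[2L]], max(lb, 0),
                 frag[act[3L]], max(lc, 0))
  ape::read.tree(text = nwk)
}

leaf_species <- function(labels, sep = "|") {
  vapply(strsplit(labels, sep, fixed = TRUE), `[`, "", 1L)
}

# descendant node-name set (inclusive) of a species-tree node
descendant_names <- function(tree, ancestor) {
  num <- node_number(tree, ancestor)
  kids <- split(tree$phylo$edge[, 2L], tree$phylo$edge[, 1L])
  out <- num
  stack <- num
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    ks <- kids[[as.character(nd)]]
    if (!is.null(ks)) { out <- c(out, ks); stack <- c(stack, ks) }
  }
  tree$names[out]
}

#' Reconcile a rooted gene tree with the species tree
#'
#' Each internal node is mapped to the last common ancestor (in the species
#' tree) of the species of its descendant leaves; a node is labelled a
#' duplication when its mapping equals the mapping of at least one child,
#' and a speciation otherwise.
#'
#' @param phy rooted binary \code{phylo}; leaf labels \code{species|gene}.
#' @param tree \code{species_tree}.
#' @param sep species/gene separator in leaf labels.
#' @return object of class \code{reconciled_gene_tree}: the tree plus
#'   per-node \code{mapping} (species-tree node names) and \code{label}
#'   (\code{"leaf"}, \code{"speciation"} or \code{"duplication"}).
#' @export
reconcile <- function(phy, tree, sep = "|") {
  if (!ape::is.rooted(phy)) stop("gene tree must be rooted")
  n_tip <- length(phy$tip.label)
  sp <- leaf_species(phy$tip.label, sep)
  unknown <- setdiff(sp, tree$phylo$tip.label)
  if (length(unknown))
    stop("gene-tree species not in species tree: ",
         paste(unique(unknown), collapse = ", "))
  nn <- n_tip + phy$Nnode
  mapping <- character(nn)
  label <- character(nn)
  mapping[seq_len(n_tip)] <- sp
  label[seq_len(n_tip)] <- "leaf"
  ord <- rev(reorder_edges_preorder_phylo(phy))
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  done <- c(rep(TRUE, n_tip), rep(FALSE, phy$Nnode))
  for (k in ord) {
    nd <- phy$edge[k, 1L]
    if (done[nd]) next
    ks <- kids[[as.character(nd)]]
    if (!all(done[ks])) next  # will be revisited via another edge later
    mapping[nd] <- tree_lca(tree, mapping[ks])
    label[nd] <- if (any(mapping[ks] == mapping[nd])) "duplication"
                 else "speciation"
    done[nd] <- TRUE
  }
  # any remaining (can happen with edge ordering): fix in repeated passes
  while (!all(done)) {
    for (nd in which(!done)) {
      ks <- kids[[as.character(nd)]]
      if (all(done[ks])) {
        mapping[nd] <- tree_lca(tree, mapping[ks])
        label[nd] <- if (any(mapping[ks] == mapping[nd])) "duplication"
                     else "speciation"
        done[nd] <- TRUE
      }
    }
  }
  structure(list(phylo = phy, mapping = mapping, label = label,
                 species = sp, sep = sep,
                 n_dup = sum(label == "duplication")),
            class = "reconciled_gene_tree")
}

reorder_edges_preorder_phylo <- function(phy) {
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
print.reconciled_gene_tree <- function(x, ...) {
  cat("Reconciled gene tree:", length(x$phylo$tip.label), "leaves,",
      x$n_dup, "duplication node(s)\n")
  invisible(x)
}

#' Root an unrooted gene tree against the species tree
#'
#' Every edge is tried as a root position; the rooting minimising the number
#' of inferred duplications after reconciliation is kept.  Ties are broken
#' by the midpoint criterion (smallest depth imbalance between the two root
#' subtrees), then by the lexicographically smallest leaf set on the first
#' child.
#'
#' @param phy unrooted \code{phylo} with >= 3 leaves.
#' @param tree \code{species_tree}.
#' @param sep species/gene separator in leaf labels.
#' @return rooted binary \code{phylo}.
#' @export
root_gene_tree <- function(phy, tree, sep = "|") {
  if (length(phy$tip.label) < 3L) stop("need at least 3 leaves")
  phy <- ape::unroot(phy)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  cands <- list()
  for (k in seq_len(nrow(phy$edge))) {
    child <- phy$edge[k, 2L]
    rooted <- root_on_edge(phy, k)
    rec <- reconcile(rooted, tree, sep)
    # midpoint imbalance: difference of max root-to-leaf path between sides
    kids <- rooted$edge[rooted$edge[, 1L] == length(rooted$tip.label) + 1L, 2L]
    hmax <- vapply(kids, function(nd) max_leaf_depth(rooted, nd), 0)
    imb <- abs(hmax[1L] - hmax[2L])
    first_child_leaves <- paste(sort(leaves_under_phylo(rooted, kids[1L])),
                                collapse = "\r")
    cands[[length(cands) + 1L]] <-
      list(rooted = rooted, ndup = rec$n_dup, imb = imb,
           key = first_child_leaves, child = child)
  }
  ndup <- vapply(cands, `[[`, 0, "ndup")
  keep <- which(ndup == min(ndup))
  if (length(keep) > 1L) {
    imb <- vapply(cands[keep], `[[`, 0, "imb")
    keep <- keep[imb <= min(imb) + 1e-9]
  }
  if (length(keep) > 1L) {
    keys <- vapply(cands[keep], `[[`, "", "key")
    keep <- keep[order(keys)][1L]
  }
  cands[[keep[1L]]]$rooted
}

root_on_edge <- function(phy, edge_idx) {
  # root at the midpoint of the given edge
  child <- phy$edge[edge_idx, 2L]
  len <- phy$edge.length[edge_idx]
  rooted <- tryCatch(
    ape::root(phy, node = child, resolve.root = TRUE, edgelabel = TRUE),
    error = function(e) NULL)
  if (is.null(rooted) || !ape::is.binary(rooted)) {
    # child is a tip: root with it as outgroup
    rooted <- ape::root(phy, outgroup = phy$tip.label[child],
                        resolve.root = TRUE)
  }
  # split the root edge lengths evenly for a midpoint-ish placement
  root <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1L] == root)
  if (length(re) == 2L) {
    tot <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- if (tot > 0) c(len / 2, tot - len / 2)
                              else c(0, 0)
    rooted$edge.length[re] <- pmax(rooted$edge.length[re], 0)
  }
  rooted
}

max_leaf_depth <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(0)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  lens <- phy$edge.length[match(kids, phy$edge[, 2L])]
  max(vapply(seq_along(kids),
             function(i) lens[i] + max_leaf_depth(phy, kids[i]), 0))
}

leaves_under_phylo <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(phy$tip.label[node])
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (nd <= n_tip) out <- c(out, phy$tip.label[nd])
    else stack <- c(stack, kids[[as.character(nd)]])
  }
  out
}

query_to_root_path <- function(rec, query_id) {
  phy <- rec$phylo
  leaf <- match(query_id, phy$tip.label)
  if (is.na(leaf)) stop("query ", query_id, " is not a leaf of the gene tree")
  n_tip <- length(phy$tip.label)
  parent <- integer(n_tip + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  out <- integer(0)
  nd <- leaf
  while (nd != n_tip + 1L) {
    nd <- parent[nd]
    out <- c(out, nd)
    if (nd == n_tip + 1L) break
  }
  out  # internal nodes from just above the leaf up to the root
}

#' Extract the ortholog group of the query at a chosen ancestor
#'
#' Walks from the query leaf towards the root collecting speciation nodes
#' whose species mapping lies at or below the chosen ancestor, and keeps the
#' one whose mapping is closest to the ancestor (the oldest qualifying
#' mapping); among several nodes sharing that mapping the one nearest the
#' root wins.  The leaves under that node form the ortholog group.
#'
#' @param rec \code{reconciled_gene_tree}.
#' @param query_id leaf label of the query gene.
#' @param ancestor species-tree node name.
#' @param tree \code{species_tree}.
#' @return list of class \code{ortholog_group} with \code{members} (leaf
#'   labels), \code{species}, \code{mapped_ancestor} and the defining node,
#'   or NULL when no speciation node qualifies (the gene is not established
#'   at this ancestor).
#' @export
extract_ortholog_group <- function(rec, query_id, ancestor, tree) {
  allowed <- descendant_names(tree, ancestor)
  path <- query_to_root_path(rec, query_id)
  qual <- path[rec$label[path] == "speciation" & rec$mapping[path] %in% allowed]
  if (!length(qual)) return(NULL)
  h <- tree$height[node_number(tree, rec$mapping[qual])]
  qual <- qual[h == max(h)]
  node <- qual[length(qual)]  # nearest the root among equals
  members <- leaves_under_phylo(rec$phylo, node)
  structure(list(members = sort(members),
                 species = sort(unique(leaf_species(members, rec$sep))),
                 defining_node = node,
                 mapped_ancestor = rec$mapping[node],
                 query = query_id),
            class = "ortholog_group")
}

#' Species under the ancestor with no ortholog in the group
#' @param group \code{ortholog_group} (or NULL: all species are missing).
#' @param tree \code{species_tree}.
#' @param ancestor node name used for extraction.
#' @export
missing_species <- function(group, tree, ancestor) {
  all_sp <- species_under(tree, ancestor)
  if (is.null(group)) return(all_sp)
  setdiff(all_sp, group$species)
}

#' Sub-family roots along the query lineage
#'
#' Speciation nodes on the query-to-root path whose path-parent is a
#' duplication node mark the establishment of new sub-families; each can be
#' scanned for lineage-specific losses independently.  Restricted to
#' mappings at or below the ancestor; returned in root-to-leaf order.
#'
#' @inheritParams extract_ortholog_group
#' @return integer vector of gene-tree node numbers (possibly empty).
#' @export
enumerate_subfamily_roots <- function(rec, query_id, ancestor, tree) {
  allowed <- descendant_names(tree, ancestor)
  path <- query_to_root_path(rec, query_id)  # leaf-to-root order
  out <- integer(0)
  for (i in seq_along(path)) {
    nd <- path[i]
    if (rec$label[nd] != "speciation") next
    if (!(rec$mapping[nd] %in% allowed)) next
    if (i < length(path) && rec$label[path[i + 1L]] == "duplication")
      out <- c(out, nd)
  }
  rev(out)  # root-to-leaf
}

#' Write a reconciled gene tree as NHX Newick with duplication tags
#' @param rec \code{reconciled_gene_tree}.
#' @param path output file.
#' @export
write_reconciled_tree <- function(rec, path) {
  phy <- rec$phylo
  n_tip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  fmt <- function(nd) {
    if (nd <= n_tip) return(phy$tip.label[nd])
    ks <- kids[[as.character(nd)]]
    tag <- sprintf("[&&NHX:D=%s:S=%s]",
                   if (rec$label[nd] == "duplication") "Y" else "N",
                   rec$mapping[nd])
    paste0("(", paste(vapply(ks, fmt, ""), collapse = ","), ")", tag)
  }
  writeLines(paste0(fmt(n_tip + 1L), ";"), path)
  invisible(path)
}
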