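# Small fixtures and independent brute-force oracles used across tests.

tree3 <- function() {
  species_tree(ape::read.tree(text = "((Hsa:6,Ptr:6)Hpa:84,Mus:90)Eth;"))
}

tree4 <- function() {
  species_tree(ape::read.tree(
    text = "(((Hsa:6,Ptr:6)Hpa:23,Mmu:29)Ctr:61,Mus:90)Eth;"))
}

tree8 <- function() example_species_tree()

# exhaustive affine-gap global alignment score: enumerate every alignment,
# charge open + len*ext per gap run, end gaps penalized
brute_global_score <- function(a, b, sub = lineageloss:::blosum62(),
                               open = 10, ext = 0.5) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > na && j > nb) { best <<- max(best, score); return(invisible()) }
    if (i <= na)
      rec(i + 1L, j, score - (if (state == 1L) ext else open + ext), 1L)
    if (j <= nb)
      rec(i, j + 1L, score - (if (state == 2L) ext else open + ext), 2L)
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, score + sub[av[i], bv[j]], 0L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# exhaustive Sankoff: minimal total cost over all ancestral labelings
brute_sankoff_cost <- function(tree, leaf_states, costs) {
  states <- c("Gene", "Pseudogene", "Absent")
  phy <- tree$phylo
  n_tip <- tree$n_tip
  nn <- n_tip + phy$Nnode
  leaf_idx <- vapply(names(leaf_states),
                     function(s) lineageloss:::node_number(tree, s), 0L)
  obs <- match(leaf_states, states)
  internals <- seq.int(n_tip + 1L, nn)
  grid <- expand.grid(rep(list(1:3), length(internals)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- integer(nn)
    assign[leaf_idx] <- obs
    assign[internals] <- as.integer(grid[r, ])
    cost <- 0
    for (k in seq_len(nrow(phy$edge))) {
      par <- phy$edge[k, 1L]; ch <- phy$edge[k, 2L]
      if (assign[ch] == 0L) next  # unobserved leaf
      cost <- cost + costs[assign[par], assign[ch]]
      if (!is.finite(cost)) break
    }
    best <- min(best, cost)
  }
  best
}

# independent reconciliation: recompute species sets and LCA mappings with ape
brute_reconcile <- function(phy, tree, sep = "|") {
  n_tip <- length(phy$tip.label)
  sp <- vapply(strsplit(phy$tip.label, sep, fixed = TRUE), `[`, "", 1L)
  sphy <- tree$phylo
  map_name <- function(species_set) {
    species_set <- unique(species_set)
    if (length(species_set) == 1L) return(species_set)
    num <- ape::getMRCA(sphy, species_set)
    c(sphy$tip.label, sphy$node.label)[num]
  }
  nn <- n_tip + phy$Nnode
  mapping <- character(nn); label <- character(nn)
  spset <- vector("list", nn)
  for (i in seq_len(n_tip)) { spset[[i]] <- sp[i]; mapping[i] <- sp[i]; label[i] <- "leaf" }
  repeat {
    progressed <- FALSE
    for (nd in seq.int(n_tip + 1L, nn)) {
      if (nzchar(mapping[nd])) next
      ks <- phy$edge[phy$edge[, 1L] == nd, 2L]
      if (!all(nzchar(mapping[ks]))) next
      spset[[nd]] <- unique(unlist(spset[ks]))
      mapping[nd] <- map_name(spset[[nd]])
      label[nd] <- if (any(mapping[ks] == mapping[nd])) "duplication" else "speciation"
      progressed <- TRUE
    }
    if (all(nzchar(mapping)) || !progressed) break
  }
  list(mapping = mapping, label = label)
}

# random additive distance matrix from a random tree; returns both
random_additive <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
  dm <- ape::cophenetic.phylo(phy)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  list(tree = phy, d = dm)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# random gene tree over a species set: random coalescent-ish topology with
# possibly repeated species
random_gene_tree <- function(species_pool, n_leaves, seed) {
  set.seed(seed)
  sp <- sample(species_pool, n_leaves, replace = TRUE)
  labs <- paste0(sp, "|g", seq_along(sp))
  phy <- ape::rtree(n_leaves)
  phy$tip.label <- labs
  phy
}

mutation_key <- function(df) {
  if (is.null(df) || !nrow(df)) return(character(0))
  sort(paste(df$kind, df$exon, df$position, sep = "/"))
}

# deterministic random protein over the 20 amino acids
ref_prot <- function(seed = 42, n = 120) {
  set.seed(seed)
  paste(sample(names(lineageloss:::PREFERRED_CODON), n, TRUE), collapse = "")
}

# exhaustive per-column parsimony over {A,C,G,T,-} with unit costs
brute_parsimony_cost <- function(phy, mat) {
  states <- c("A", "C", "G", "T", "-")
  n_tip <- length(phy$tip.label)
  nn <- n_tip + phy$Nnode
  internals <- seq.int(n_tip + 1L, nn)
  grid <- as.matrix(expand.grid(rep(list(1:5), length(internals))))
  total <- 0
  for (col in seq_len(ncol(mat))) {
    obs <- match(mat[phy$tip.label, col], states)
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      assign <- integer(nn)
      assign[seq_len(n_tip)] <- obs
      assign[internals] <- grid[r, ]
      cost <- 0
      for (k in seq_len(nrow(phy$edge))) {
        par <- phy$edge[k, 1L]; ch <- phy$edge[k, 2L]
        if (is.na(assign[ch])) next  # ambiguous leaf matches anything
        if (!is.na(assign[par]) && assign[par] != assign[ch]) cost <- cost + 1
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# exhaustive minimal loss-set search for the Dollo model
brute_min_losses <- function(presence, tree) {
  present <- names(presence)[presence]
  birth <- tree_lca(tree, present)
  presence <- presence[names(presence) %in% species_under(tree, birth)]
  present <- names(presence)[presence]
  absent <- names(presence)[!presence]
  cand_branches <- setdiff(lineageloss:::descendant_names(tree, birth), birth)
  for (k in 0:length(cand_branches)) {
    sets <- if (k == 0) list(character(0)) else
      combn(cand_branches, k, simplify = FALSE)
    for (s in sets) {
      covered <- function(sp) {
        path <- branch_path(tree, birth, sp)
        sum(path %in% s)
      }
      n_loss <- vapply(names(presence), covered, 0)
      okA <- all(n_loss[absent] == 1)
      okP <- all(n_loss[present] == 0)
      if (length(absent) == 0) okA <- TRUE
      if (okA && okP) return(list(k = k, losses = s))
    }
  }
  NULL
}

leaves_under_root_child <- function(phy) {
  root <- length(phy$tip.label) + 1L
  kids <- phy$edge[phy$edge[, 1L] == root, 2L]
  lineageloss:::leaves_under_phylo(phy, kids[1L])
}

report_json_string <- function(rep) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_report_json(rep, f)
  paste(readLines(f), collapse = "\n")
}
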