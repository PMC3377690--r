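#' Dollo-like inference of the gene birth node and loss branches
#'
#' The birth node is the last common ancestor of all species carrying the
#' gene; losses are placed on the stems of the maximal absent-only clades
#' under the birth node, so every absent leaf has exactly one loss on its
#' path and no present leaf has any.
#'
#' @param presence named logical vector (TRUE = present) over the studied
#'   species.
#' @param tree \code{species_tree}.
#' @return list with \code{birth} (node name) and \code{losses} (character
#'   vector of branch names, each branch named by its child node).
#' @export
dollo_losses <- function(presence, tree) {
  present <- names(presence)[presence]
  absent <- names(presence)[!presence]
  if (!length(present)) stop("no present species: cannot place a gene birth")
  birth <- tree_lca(tree, present)
  absent <- intersect(absent, species_under(tree, birth))
  if (!length(absent)) return(list(birth = birth, losses = character(0)))
  # a node is absent-only if all studied leaves under it are absent
  losses <- character(0)
  walk <- function(name) {
    under <- intersect(species_under(tree, name), names(presence))
    if (length(under) && all(under %in% absent)) {
      losses <<- c(losses, name)   # loss on this node's stem branch
      return(invisible())
    }
    if (!is_leaf(tree, name))
      for (ch in children_names(tree, name)) walk(ch)
  }
  for (ch in children_names(tree, birth)) walk(ch)
  list(birth = birth, losses = losses)
}

#' Default state-transition costs for gene/pseudogene/absent characters
#'
#' Encodes Dollo-like irreversibility: a gene can decay to a pseudogene or
#' disappear, and a pseudogene can erode to undetectability, but no state
#' is ever regained.
#' @export
default_state_costs <- function() {
  states <- c("Gene", "Pseudogene", "Absent")
  m <- matrix(Inf, 3, 3, dimnames = list(states, states))
  diag(m) <- 0
  m["Gene", "Pseudogene"] <- 1
  m["Gene", "Absent"] <- 1
  m["Pseudogene", "Absent"] <- 1
  m
}

#' Sankoff parsimony over {Gene, Pseudogene, Absent} on the species tree
#'
#' Leaf verdicts map Present and Saved to Gene, Pseudogene to Pseudogene,
#' and Lost to Absent.  The minimal-total-cost ancestral assignment under
#' the (by default irreversible) cost matrix is computed by dynamic
#' programming; ties are resolved in a preorder pass preferring Gene, then
#' Pseudogene.
#'
#' @param leaf_states named character vector over the studied species with
#'   values in Present/Saved/Pseudogene/Lost (or directly
#'   Gene/Pseudogene/Absent).
#' @param tree \code{species_tree}.
#' @param costs 3x3 cost matrix (see \code{default_state_costs}).
#' @return list with \code{states} (named character vector over all tree
#'   nodes restricted to the studied subtree; species not studied are NA)
#'   and \code{cost}.
#' @export
sankoff_states <- function(leaf_states, tree, costs = default_state_costs()) {
  states <- c("Gene", "Pseudogene", "Absent")
  map <- c(Present = "Gene", Saved = "Gene", Pseudogene = "Pseudogene",
           Lost = "Absent", Gene = "Gene", Absent = "Absent")
  obs <- map[leaf_states]
  if (anyNA(obs)) stop("unknown leaf state: ",
                       paste(leaf_states[is.na(obs)], collapse = ", "))
  names(obs) <- names(leaf_states)
  phy <- tree$phylo
  n_tip <- tree$n_tip
  nn <- n_tip + phy$Nnode
  BIG <- 1e12
  S <- matrix(BIG, nn, 3L)
  studied <- rep(FALSE, nn)
  for (sp in names(obs)) {
    i <- node_number(tree, sp)
    S[i, ] <- BIG
    S[i, match(obs[[sp]], states)] <- 0
    studied[i] <- TRUE
  }
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  done <- c(studied[seq_len(n_tip)] | TRUE, rep(FALSE, phy$Nnode))
  # unstudied leaves contribute nothing
  for (i in seq_len(n_tip)) if (!studied[i]) S[i, ] <- 0
  cost_no_inf <- costs
  cost_no_inf[!is.finite(cost_no_inf)] <- BIG
  repeat {
    progressed <- FALSE
    for (nd in seq.int(n_tip + 1L, nn)) {
      if (done[nd]) next
      ks <- kids[[as.character(nd)]]
      if (!all(done[ks])) next
      v <- numeric(3L)
      for (ch in ks) {
        inc <- vapply(1:3, function(s)
          min(cost_no_inf[s, ] + S[ch, ]), 0)
        v <- v + inc
      }
      S[nd, ] <- pmin(v, BIG)
      done[nd] <- TRUE
      progressed <- TRUE
    }
    if (all(done) || !progressed) break
  }
  root <- n_tip + 1L
  assign <- rep(NA_character_, nn)
  pref <- c(1L, 2L, 3L)  # Gene, then Pseudogene, then Absent on ties
  pickmin <- function(v) pref[which.min(v[pref])]
  assign[root] <- states[pickmin(S[root, ])]
  for (k in reorder_edges_preorder_phylo(phy)) {
    par <- phy$edge[k, 1L]; ch <- phy$edge[k, 2L]
    ps <- match(assign[par], states)
    v <- cost_no_inf[ps, ] + S[ch, ]
    assign[ch] <- states[pickmin(v)]
  }
  # species outside the study keep NA leaf states but ancestors are reported
  for (i in seq_len(n_tip)) if (!studied[i]) assign[i] <- NA_character_
  total <- min(S[root, ])
  if (total >= BIG)
    stop("no finite-cost assignment: leaf states incompatible with the cost matrix")
  list(states = setNames(assign, tree$names), cost = total)
}

#' Place branch events from ancestral states
#'
#' An event sits on every branch whose child state differs from its parent
#' state: Gene to Pseudogene is a pseudogenization, Gene or Pseudogene to
#' Absent is a gene loss.  The gene birth is the highest node assigned
#' Gene.  Pseudogenization branches are decorated with the mutations that
#' the lineage scan attributed to them.
#'
#' @param states output of \code{sankoff_states}.
#' @param tree \code{species_tree}.
#' @param mutation_reports optional named list (per species) of mutation
#'   data.frames with a \code{branch} column.
#' @return list of class \code{event_placements}: \code{birth} node name,
#'   data.frame \code{events} (branch, event), and
#'   \code{supporting_mutations} (named by branch).
#' @export
place_events <- function(states, tree, mutation_reports = NULL) {
  st <- states$states
  gene_nodes <- names(st)[!is.na(st) & st == "Gene"]
  birth <- NA_character_
  if (length(gene_nodes)) {
    # highest = the one that is an ancestor of all others or has max height
    h <- tree$height[node_number(tree, gene_nodes)]
    birth <- gene_nodes[which.max(h)]
  }
  events <- list()
  for (nm in names(st)) {
    p <- parent_name(tree, nm)
    if (is.na(p) || is.na(st[[nm]]) || is.na(st[[p]])) next
    if (st[[p]] == st[[nm]]) next
    ev <- if (st[[p]] == "Gene" && st[[nm]] == "Pseudogene") "pseudogenization"
          else if (st[[nm]] == "Absent") "gene_loss"
          else stop("state transition ", st[[p]], "->", st[[nm]],
                    " has infinite cost; inconsistent assignment")
    events[[length(events) + 1L]] <- data.frame(branch = nm, event = ev,
                                                stringsAsFactors = FALSE)
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(branch = character(), event = character(),
                            stringsAsFactors = FALSE)
  support <- list()
  allmut <- if (length(mutation_reports))
    unique(do.call(rbind, mutation_reports)) else NULL
  if (!is.null(allmut) && nrow(events)) {
    for (b in events$branch[events$event == "pseudogenization"]) {
      sel <- allmut[allmut$branch == b, , drop = FALSE]
      if (nrow(sel)) support[[b]] <- sel
    }
  }
  structure(list(birth = birth, events = events,
                 supporting_mutations = support),
            class = "event_placements")
}
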