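#' Choose the sequence set for ancestral reconstruction
#'
#' At most one sequence per species: for species with several, the one with
#' the highest protein identity to the scan reference is kept.  Known
#' orthologs whose identity falls below \code{100 - max_divergence_pct} are
#' dropped (too divergent to help the reconstruction); candidate sequences
#' under scan are always retained.
#'
#' @param candidates data.frame with columns species, id, seq (locus DNA)
#'   and identity_pct (protein identity to the reference).
#' @param knowns same layout for known orthologs.
#' @param max_divergence_pct divergence cutoff in percent.
#' @return data.frame with one row per retained species and a logical
#'   column \code{is_candidate}.
#' @export
select_reconstruction_set <- function(candidates, knowns,
                                      max_divergence_pct = 60) {
  if (nrow(candidates) < 1L) stop("need at least one candidate sequence")
  keep_best <- function(df) {
    df <- df[order(-df$identity_pct), , drop = FALSE]
    df[!duplicated(df$species), , drop = FALSE]
  }
  cand <- keep_best(candidates)
  cand$is_candidate <- TRUE
  kn <- knowns[!(knowns$species %in% cand$species), , drop = FALSE]
  kn <- kn[kn$identity_pct >= 100 - max_divergence_pct, , drop = FALSE]
  kn <- keep_best(kn)
  if (nrow(kn)) kn$is_candidate <- FALSE
  out <- rbind(cand, if (nrow(kn)) kn)
  if (nrow(out) < 3L)
    stop("insufficient taxa for reconstruction: ", nrow(out),
         " sequence(s) after filtering")
  rownames(out) <- NULL
  out
}

# shared k-mer distance between two sequences: 1 - |shared k-mers| / min(#)
kmer_distance <- function(a, b, k = 8L) {
  ka <- unique(substring(a, seq_len(max(nchar(a) - k + 1L, 1L)),
                         seq_len(max(nchar(a) - k + 1L, 1L)) + k - 1L))
  kb <- unique(substring(b, seq_len(max(nchar(b) - k + 1L, 1L)),
                         seq_len(max(nchar(b) - k + 1L, 1L)) + k - 1L))
  sh <- length(intersect(ka, kb))
  1 - sh / max(1L, min(length(ka), length(kb)))
}

# progressive MSA of DNA sequences; guide = UPGMA on shared k-mer distances
progressive_msa <- function(seqs, band_extra = 300L) {
  n <- length(seqs)
  if (n == 1L) return(setNames(seqs, names(seqs)))
  nms <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      d[i, j] <- d[j, i] <- kmer_distance(seqs[[i]], seqs[[j]])
  hc <- hclust(as.dist(d), method = "average")
  groups <- lapply(seq_len(n), function(i) setNames(seqs[i], nms[i]))
  sub <- dna_score_matrix()
  for (m in seq_len(nrow(hc$merge))) {
    a <- hc$merge[m, 1L]; b <- hc$merge[m, 2L]
    ga <- if (a < 0) groups[[-a]] else groups[[n + a]]
    gb <- if (b < 0) groups[[-b]] else groups[[n + b]]
    band <- abs(nchar(ga[[1L]]) - nchar(gb[[1L]])) + band_extra
    res <- .profile_align_cpp(unlist(ga), unlist(gb), sub,
                              6, 1, -2, as.integer(band))
    merged <- c(setNames(as.character(res$a), names(ga)),
                setNames(as.character(res$b), names(gb)))
    groups[[n + m]] <- merged
  }
  out <- groups[[n + nrow(hc$merge)]]
  out[nms]
}

#' Guided multiple alignment with coding-region compaction
#'
#' Aligns the locus sequences with a progressive profile aligner (UPGMA
#' guide on shared-k-mer distances), then keeps only the alignment columns
#' that fall inside the projection of the reference exons, extended by
#' \code{flank} columns at each junction so splice dinucleotides stay
#' observable.  Column maps back to each row's local coordinates are kept
#' so mutation positions can be reported in locus coordinates.
#'
#' @param seqs named character vector of locus DNA, one per taxon, all in
#'   transcript orientation.
#' @param reference_species name of the annotated reference row.
#' @param reference_exons 2-column matrix of 0-based half-open exon
#'   intervals in the reference row's local coordinates.
#' @param flank columns of intron context kept at each junction.
#' @return object of class \code{compacted_alignment}: \code{rows} (gapped
#'   strings), \code{column_map} (taxa x columns matrix of 0-based local
#'   positions, NA at gaps), \code{exon_cols} (list of 1-based inclusive
#'   column ranges per exon), \code{low_confidence} flag per exon.
#' @export
build_guided_alignment <- function(seqs, reference_species, reference_exons,
                                   flank = 20L) {
  if (!reference_species %in% names(seqs))
    stop("reference species ", reference_species, " absent from sequence set")
  aln <- progressive_msa(seqs)
  L <- nchar(aln[[1L]])
  mat <- do.call(rbind, strsplit(unlist(aln), "", fixed = TRUE))
  rownames(mat) <- names(aln)
  ref <- mat[reference_species, ]
  ref_pos <- cumsum(ref != "-") - 1L   # 0-based local position per column
  ref_pos[ref == "-"] <- NA_integer_
  # column index of each reference local position
  col_of <- rep(NA_integer_, sum(ref != "-"))
  col_of[ref_pos[!is.na(ref_pos)] + 1L] <- which(ref != "-")
  n_exonic <- sum(reference_exons[, 2L] - reference_exons[, 1L])
  covered <- sum(!is.na(col_of[unlist(mapply(function(s, e) seq(s + 1L, e),
                    reference_exons[, 1L], reference_exons[, 2L],
                    SIMPLIFY = FALSE))]))
  if (covered < 0.5 * n_exonic)
    stop("projection failure: reference aligns fewer than half of its exonic positions")
  ne <- nrow(reference_exons)
  exon_col_rng <- matrix(0L, ne, 2L)
  for (e in seq_len(ne)) {
    exon_col_rng[e, ] <- c(col_of[reference_exons[e, 1L] + 1L],
                           col_of[reference_exons[e, 2L]])
  }
  # retained columns: exon ranges +/- flank, merged
  keepmask <- rep(FALSE, L)
  for (e in seq_len(ne)) {
    lo <- max(1L, exon_col_rng[e, 1L] - flank)
    hi <- min(L, exon_col_rng[e, 2L] + flank)
    keepmask[lo:hi] <- TRUE
  }
  keep <- which(keepmask)
  # per-row local coordinates
  cmap <- matrix(NA_integer_, nrow(mat), L,
                 dimnames = list(rownames(mat), NULL))
  for (r in seq_len(nrow(mat))) {
    nz <- mat[r, ] != "-"
    cmap[r, nz] <- seq_len(sum(nz)) - 1L
  }
  newcol <- match(seq_len(L), keep)   # original col -> compacted col
  exon_cols <- lapply(seq_len(ne), function(e)
    c(newcol[exon_col_rng[e, 1L]], newcol[exon_col_rng[e, 2L]]))
  cmat <- mat[, keep, drop = FALSE]
  # projection-quality flag: exon boundary aligning to gap in >= half the
  # non-reference rows suggests the reading frame may be misprojected
  low_conf <- vapply(seq_len(ne), function(e) {
    rng <- exon_cols[[e]]
    bcols <- unique(c(max(1L, rng[1L]):min(rng[1L] + 2L, ncol(cmat)),
                      max(1L, rng[2L] - 2L):rng[2L]))
    others <- setdiff(rownames(cmat), reference_species)
    if (!length(others)) return(FALSE)
    frac_gap <- mean(vapply(others, function(r)
      sum(cmat[r, bcols] == "-") > 2L, TRUE))
    frac_gap >= 0.5
  }, TRUE)
  structure(list(rows = apply(cmat, 1L, paste, collapse = ""),
                 matrix = cmat,
                 column_map = cmap[, keep, drop = FALSE],
                 exon_cols = exon_cols,
                 reference_species = reference_species,
                 flank = flank,
                 low_confidence = low_conf),
            class = "compacted_alignment")
}

#' @export
print.compacted_alignment <- function(x, ...) {
  cat("Compacted alignment:", nrow(x$matrix), "rows x", ncol(x$matrix),
      "columns,", length(x$exon_cols), "projected exon(s)\n")
  invisible(x)
}

#' Ancestral sequence reconstruction by Sankoff parsimony
#'
#' Per-column Sankoff parsimony over the 5-state alphabet {A,C,G,T,-} with
#' unit substitution cost and unit gap-transition cost.  Ambiguities are
#' resolved in a preorder pass preferring the parent's state, then
#' alphabetical order.  The guide tree is either a neighbor-joining tree on
#' TN93 distances over the compacted columns (default) or a supplied rooted
#' tree (e.g. the pruned species tree).
#'
#' @param aln \code{compacted_alignment}.
#' @param guide rooted binary \code{phylo} whose tips are the alignment
#'   taxa, or NULL to estimate one (NJ on TN93, midpoint-rooted).
#' @return list of class \code{ancestral_reconstruction}: \code{tree} (the
#'   rooted guide tree with named internal nodes), \code{rows} (ancestral
#'   gapped strings named by internal node), \code{cost} (total parsimony
#'   cost).
#' @export
reconstruct_ancestors <- function(aln, guide = NULL) {
  mat <- aln$matrix
  if (nrow(mat) < 3L) stop("need at least 3 rows for reconstruction")
  taxa <- rownames(mat)
  if (is.null(guide)) {
    guide <- nj_tn93_guide(aln)
  }
  if (!ape::is.rooted(guide)) stop("guide tree must be rooted")
  if (!setequal(guide$tip.label, taxa))
    stop("guide tree tips must match alignment taxa")
  if (is.null(guide$node.label) || any(!nzchar(guide$node.label)))
    guide$node.label <- paste0("anc", seq_len(guide$Nnode))
  states <- c("A", "C", "G", "T", "-")
  cost <- 1 - diag(5)   # unit substitution and gap-transition cost
  n_tip <- length(guide$tip.label)
  nn <- n_tip + guide$Nnode
  L <- ncol(mat)
  # leaf state costs: 0 for observed state, Inf otherwise; N matches all
  S <- vector("list", nn)
  BIG <- 1e9
  for (i in seq_len(n_tip)) {
    obs <- mat[guide$tip.label[i], ]
    m <- matrix(BIG, 5L, L)
    for (s in seq_along(states)) m[s, obs == states[s]] <- 0
    m[, !(obs %in% states)] <- 0   # N or other ambiguity
    S[[i]] <- m
  }
  kids <- split(guide$edge[, 2L], guide$edge[, 1L])
  done <- c(rep(TRUE, n_tip), rep(FALSE, guide$Nnode))
  repeat {
    progressed <- FALSE
    for (nd in seq.int(n_tip + 1L, nn)) {
      if (done[nd]) next
      ks <- kids[[as.character(nd)]]
      if (!all(done[ks])) next
      m <- matrix(0, 5L, L)
      for (ch in ks) {
        Sc <- S[[ch]]
        # min over child state of (cost + child cost), for each parent state
        inc <- matrix(0, 5L, L)
        for (s in 1:5) {
          v <- Sc + cost[, s]        # recycles cost column over columns? no:
          # cost[, s] is length 5; sweep over rows
          v <- Sc + matrix(cost[, s], 5L, L)
          inc[s, ] <- apply(v, 2L, min)
        }
        m <- m + inc
      }
      S[[nd]] <- m
      done[nd] <- TRUE
      progressed <- TRUE
    }
    if (all(done) || !progressed) break
  }
  root <- n_tip + 1L
  assign_states <- matrix("", nn, L)
  # root: min cost, ties alphabetical (states order A,C,G,T,-)
  pick <- function(scores) which.min(scores)   # which.min is first = preference order
  root_idx <- apply(S[[root]], 2L, pick)
  assign_states[root, ] <- states[root_idx]
  # preorder assignment
  for (k in reorder_edges_preorder_phylo(guide)) {
    par <- guide$edge[k, 1L]; ch <- guide$edge[k, 2L]
    if (ch <= n_tip) next
    ps <- match(assign_states[par, ], states)
    Sc <- S[[ch]]
    chosen <- integer(L)
    for (s in 1:5) {
      colsel <- ps == s
      if (!any(colsel)) next
      v <- Sc[, colsel, drop = FALSE] + matrix(cost[, s], 5L, sum(colsel))
      # prefer parent state on ties: reorder candidate states so parent first
      ordst <- c(s, setdiff(1:5, s))
      best <- apply(v[ordst, , drop = FALSE], 2L, which.min)
      chosen[colsel] <- ordst[best]
    }
    assign_states[ch, ] <- states[chosen]
  }
  anc_rows <- apply(assign_states[seq.int(n_tip + 1L, nn), , drop = FALSE],
                    1L, paste, collapse = "")
  names(anc_rows) <- guide$node.label
  total_cost <- sum(apply(S[[root]], 2L, min))
  structure(list(tree = guide, rows = anc_rows, cost = total_cost),
            class = "ancestral_reconstruction")
}

nj_tn93_guide <- function(aln) {
  mat <- aln$matrix
  bin <- ape::as.DNAbin(tolower(mat))
  d <- ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
  phy <- build_nj(as.matrix(d))
  mid <- tryCatch(phangorn::midpoint(phy), error = function(e) NULL)
  if (is.null(mid) || !ape::is.rooted(mid)) {
    mid <- ape::root(phy, outgroup = phy$tip.label[1L], resolve.root = TRUE)
  }
  mid
}
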