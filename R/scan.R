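STOP_CODONS <- c("TAA", "TAG", "TGA")
DISABLING_KINDS <- c("nonsense", "frameshift", "splice_donor",
                     "splice_acceptor", "start_loss", "stop_loss",
                     "exon_loss")

empty_mutations <- function() {
  data.frame(kind = character(), exon = integer(), position = integer(),
             detail = character(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Scan one descendant row against its ancestor row for disabling mutations
#'
#' Reads both rows codon-by-codon inside each projected exon (the reading
#' frame is carried by the reference row of the alignment) and emits typed
#' mutations: \code{nonsense} when the descendant gains an in-frame stop the
#' ancestor lacks; \code{insertion}/\code{deletion} for gap runs present in
#' only one row (with a companion \code{frameshift} when the indel length is
#' not a multiple of 3); \code{start_loss}/\code{stop_loss} at the projected
#' initiator and terminator codons; \code{splice_donor}/\code{splice_acceptor}
#' when a canonical GT/AG dinucleotide in the retained junction flank is
#' altered; \code{exon_loss} when a projected exon is >= 90 percent gap in
#' the descendant but < 50 percent gap in the ancestor.  Positions are
#' codon indices (nonsense, start/stop) or nt offsets (indels) within the
#' exon, 1-based, in projection coordinates.
#'
#' @param desc,anc gapped rows (strings or character vectors) of equal
#'   length, descendant and ancestor.
#' @param aln the \code{compacted_alignment} providing the exon projection
#'   and reference reading frame.
#' @return data.frame of mutations (kind, exon, position, detail, length).
#' @export
scan_pair <- function(desc, anc, aln) {
  dv <- if (length(desc) == 1L) strsplit(desc, "", fixed = TRUE)[[1L]] else desc
  av <- if (length(anc) == 1L) strsplit(anc, "", fixed = TRUE)[[1L]] else anc
  if (length(dv) != length(av)) stop("rows differ in length")
  refv <- aln$matrix[aln$reference_species, ]
  exon_cols <- aln$exon_cols
  ne <- length(exon_cols)
  out <- list()
  emit <- function(kind, exon, position, detail = "", len = NA_integer_) {
    out[[length(out) + 1L]] <<- data.frame(
      kind = kind, exon = exon, position = as.integer(position),
      detail = detail, length = as.integer(len), stringsAsFactors = FALSE)
  }
  # exon loss first; lost exons are not scanned codon-wise
  lost <- logical(ne)
  for (e in seq_len(ne)) {
    rng <- exon_cols[[e]]
    cols <- seq(rng[1L], rng[2L])
    gap_d <- mean(dv[cols] == "-")
    gap_a <- mean(av[cols] == "-")
    if (gap_d >= 0.9 && gap_a < 0.5) {
      emit("exon_loss", e, 1L, sprintf("%.0f%% gap", 100 * gap_d))
      lost[e] <- TRUE
    }
  }
  # codon-wise scan in the projected frame (reference row defines codons,
  # phase carried across exons)
  codon_phase <- 0L
  codon_cols <- integer(0)
  codon_ct <- integer(ne)  # codons per exon seen so far
  first_codon <- TRUE
  for (e in seq_len(ne)) {
    rng <- exon_cols[[e]]
    cols <- seq(rng[1L], rng[2L])
    refnt <- cols[refv[cols] != "-"]
    for (cl in refnt) {
      codon_cols <- c(codon_cols, cl)
      if (length(codon_cols) == 3L) {
        codon_ct[e] <- codon_ct[e] + 1L
        if (!lost[e]) {
          dcod <- paste(dv[codon_cols], collapse = "")
          acod <- paste(av[codon_cols], collapse = "")
          if (!grepl("-", dcod, fixed = TRUE)) {
            if (first_codon) {
              if (acod == "ATG" && dcod != "ATG")
                emit("start_loss", e, codon_ct[e], dcod)
            } else if (dcod %in% STOP_CODONS && !(acod %in% STOP_CODONS)) {
              # terminal stop handled as stop_loss below; interior gain:
              emit("nonsense", e, codon_ct[e], dcod)
            }
          }
          if (first_codon && grepl("-", dcod, fixed = TRUE) &&
              acod == "ATG")
            emit("start_loss", e, codon_ct[e], dcod)
        }
        if (first_codon) first_codon <- FALSE
        last_codon_info <- list(exon = e, idx = codon_ct[e],
                                cols = codon_cols)
        codon_cols <- integer(0)
      }
    }
  }
  # terminator: last full codon of the projection
  if (exists("last_codon_info", inherits = FALSE)) {
    lc <- last_codon_info
    if (!lost[lc$exon]) {
      acod <- paste(av[lc$cols], collapse = "")
      dcod <- paste(dv[lc$cols], collapse = "")
      if (acod %in% STOP_CODONS && !(dcod %in% STOP_CODONS))
        emit("stop_loss", lc$exon, lc$idx, dcod)
    }
  }
  # indels: maximal runs inside exons where exactly one row is gapped
  for (e in seq_len(ne)) {
    if (lost[e]) next
    rng <- exon_cols[[e]]
    cols <- seq(rng[1L], rng[2L])
    dgap <- dv[cols] == "-"; agap <- av[cols] == "-"
    del <- dgap & !agap      # descendant lost nucleotides
    ins <- agap & !dgap      # descendant gained nucleotides
    for (runtype in c("deletion", "insertion")) {
      v <- if (runtype == "deletion") del else ins
      # the row that carries the residues of the indel block
      carrier <- if (runtype == "deletion") av[cols] else dv[cols]
      r <- rle(v)
      pos <- cumsum(c(1L, r$lengths))
      for (k in which(r$values)) {
        len <- r$lengths[k]
        # nt offset within the exon projection, 1-based; indels in repeated
        # context are canonicalised by left alignment
        start_off <- pos[k]
        end_off <- start_off + len - 1L
        while (start_off > 1L && !is.na(carrier[start_off - 1L]) &&
               carrier[start_off - 1L] != "-" &&
               carrier[start_off - 1L] == carrier[end_off]) {
          start_off <- start_off - 1L; end_off <- end_off - 1L
        }
        emit(runtype, e, start_off, "", len)
        if (len %% 3L != 0L)
          emit("frameshift", e, start_off, sprintf("%s of %d nt", runtype, len), len)
      }
    }
  }
  # splice sites: junction j sits after exon j; donor = 2 columns after the
  # exon end, acceptor = 2 columns before the next exon start
  if (ne > 1L) {
    for (j in seq_len(ne - 1L)) {
      # junctions adjacent to a lost exon carry no splice information
      if (lost[j] || lost[j + 1L]) next
      dn_cols <- exon_cols[[j]][2L] + c(1L, 2L)
      ac_cols <- exon_cols[[j + 1L]][1L] - c(2L, 1L)
      if (max(dn_cols) <= length(dv)) {
        a <- paste(av[dn_cols], collapse = ""); d <- paste(dv[dn_cols], collapse = "")
        if (a == "GT" && d != "GT") emit("splice_donor", j, 1L, d)
      }
      if (min(ac_cols) >= 1L) {
        a <- paste(av[ac_cols], collapse = ""); d <- paste(dv[ac_cols], collapse = "")
        if (a == "AG" && d != "AG") emit("splice_acceptor", j, 1L, d)
      }
    }
  }
  if (!length(out)) return(empty_mutations())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan a lineage branch-by-branch and attribute mutations
#'
#' For every branch on the path from the root of the reconstruction tree to
#' each target taxon, compares the child row (contemporary or ancestral)
#' with its parent-ancestor row via \code{scan_pair}.  Mutations found on an
#' ancestor-vs-ancestor comparison are attributed to that internal branch,
#' so an event shared by sister species is reported once, on their stem.
#'
#' @param aln \code{compacted_alignment}.
#' @param rec \code{ancestral_reconstruction} on the same alignment.
#' @param targets taxa (leaf names) whose lineages are scanned.
#' @return named list (one per target) of mutation data.frames with a
#'   \code{branch} column (branch = name of its child node).
#' @export
scan_lineage <- function(aln, rec, targets) {
  guide <- rec$tree
  n_tip <- length(guide$tip.label)
  node_names <- c(guide$tip.label, guide$node.label)
  row_of <- function(name) {
    if (name %in% names(rec$rows)) rec$rows[[name]]
    else aln$rows[[name]]
  }
  parent <- integer(n_tip + guide$Nnode)
  parent[guide$edge[, 2L]] <- guide$edge[, 1L]
  branch_cache <- new.env()
  scan_branch <- function(child_num) {
    key <- as.character(child_num)
    if (!is.null(branch_cache[[key]])) return(branch_cache[[key]])
    par <- parent[child_num]
    muts <- scan_pair(row_of(node_names[child_num]),
                      row_of(node_names[par]), aln)
    if (nrow(muts)) muts$branch <- node_names[child_num]
    else muts$branch <- character(0)
    branch_cache[[key]] <- muts
    muts
  }
  out <- list()
  root <- n_tip + 1L
  for (tg in targets) {
    leaf <- match(tg, guide$tip.label)
    if (is.na(leaf)) stop("target ", tg, " not in reconstruction tree")
    chain <- leaf
    nd <- leaf
    while (nd != root) { nd <- parent[nd]; chain <- c(chain, nd) }
    branches <- chain[chain != root]   # child nodes of path branches
    muts <- do.call(rbind, lapply(branches, scan_branch))
    if (is.null(muts)) muts <- cbind(empty_mutations(),
                                     data.frame(branch = character()))
    rownames(muts) <- NULL
    out[[tg]] <- muts
  }
  out
}

#' Classify a scanned sequence as intact or pseudogene
#'
#' Pseudogene iff the mutation report for the target's lineage contains at
#' least one disabling mutation (nonsense, frameshift, splice-site change,
#' start/stop loss or exon loss).  In-frame indels alone do not condemn a
#' sequence.
#'
#' @param report mutation data.frame from \code{scan_lineage} for one
#'   target.
#' @return \code{"pseudogene"} or \code{"intact"}.
#' @export
classify_sequence <- function(report) {
  if (nrow(report) && any(report$kind %in% DISABLING_KINDS)) "pseudogene"
  else "intact"
}

#' Run the nucleotide-level forensic stage on a simulated family
#'
#' Convenience driver for validation: takes the loci of every species whose
#' genome still carries the gene region, aligns them guided by the closest
#' annotated reference, reconstructs ancestors along the pruned species
#' tree, and scans the lineages of the pseudogenized species.
#'
#' @param sim a \code{sim_family} from \code{simulate_family}.
#' @param flank compaction flank (nt) at each junction.
#' @return list with the alignment, the reconstruction and per-target
#'   mutation reports.
#' @export
scan_family <- function(sim, flank = 20L) {
  led <- sim$ledger$verdicts
  keep <- names(led)[led != "Lost"]
  targets <- names(led)[led == "Pseudogene"]
  if (length(keep) < 3L) stop("fewer than 3 genomes carry the gene region")
  seqs <- vapply(keep, function(sp) sim$genomes[[sp]][[1L]], "")
  ann <- sim$annotations
  ann_sp <- intersect(keep, ann$species)
  if (!length(ann_sp)) stop("no annotated reference species available")
  pool <- if (length(targets)) targets else keep
  mean_div <- vapply(ann_sp, function(s)
    mean(vapply(setdiff(pool, s), function(t2)
      divergence_time(sim$tree, s, t2), 0)), 0)
  ref_sp <- ann_sp[which.min(mean_div)]
  ref_exons <- ann$exons[[match(ref_sp, ann$species)]]
  aln <- build_guided_alignment(seqs, ref_sp, ref_exons, flank = flank)
  guide <- prune_species_tree(sim$tree, keep)$phylo
  rec <- reconstruct_ancestors(aln, guide)
  reports <- if (length(targets)) scan_lineage(aln, rec, targets) else list()
  list(alignment = aln, reconstruction = rec, reports = reports)
}
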