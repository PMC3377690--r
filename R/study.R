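#' Run a full lineage-loss study for one query protein
#'
#' Phase 1 gathers homologs of the query from the proteomes, builds and
#' reconciles a gene tree, extracts the ortholog group at the configured
#' ancestor and lists the species with no ortholog.  In simple mode those
#' species are declared Lost and events are placed by Dollo-like parsimony.
#' In complete mode each missing species' genome is screened by translated
#' search; chained candidate loci are tested for orthology phylogenetically,
#' checked against existing annotations, gene-predicted, and routed by the
#' length/similarity gate either to the protein-level divergence-consistency
#' test or to a joint nucleotide-level study (guided alignment, ancestral
#' reconstruction, branch-by-branch mutation scan).  Final verdicts are
#' synthesised into branch events by Sankoff parsimony.
#'
#' @param query id of the query protein in \code{proteome}, or a one-row
#'   \code{seq_records}.
#' @param proteome \code{seq_records} of all known proteins.
#' @param tree \code{species_tree}.
#' @param config \code{run_config}.
#' @param genomes named list (species -> named list of chromosome strings);
#'   required in complete mode.
#' @param annotations \code{exon_annotations} or NULL.
#' @return object of class \code{study_report}.
#' @export
run_study <- function(query, proteome, tree, config, genomes = NULL,
                      annotations = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!config$ancestor %in% tree$names)
    stop("configured ancestor ", config$ancestor, " not in species tree")
  if (config$mode == "complete" && is.null(genomes))
    stop("complete mode requires genome sequences")
  set.seed(config$seed)
  th <- config$thresholds
  if (is.character(query)) {
    i <- match(query, proteome$id)
    if (is.na(query) || is.na(i)) stop("query ", query, " not found in proteome")
    query <- proteome[i, , drop = FALSE]
  }
  if (!query$species %in% tree$phylo$tip.label)
    stop("query species ", query$species, " not in species tree")
  warnings <- character(0)
  evidence <- list()

  ## Phase 1: homologs, gene tree, ortholog group -------------------------
  fam <- gather_homologs(query, proteome, th)
  group <- NULL
  rec <- NULL
  if (nrow(fam) >= 3L) {
    d <- pairwise_distances(fam)
    rooted <- root_gene_tree(build_nj(d), tree)
    rec <- reconcile(rooted, tree)
    group <- extract_ortholog_group(rec, query$id, config$ancestor, tree)
  }
  if (is.null(group)) {
    # not enough homologs for a tree, or no qualifying speciation node:
    # the group degenerates to the gathered homologs
    group <- structure(list(members = fam$id,
                            species = sort(unique(fam$species)),
                            defining_node = NA, mapped_ancestor = NA,
                            query = query$id), class = "ortholog_group")
    warnings <- c(warnings,
                  "ortholog group read directly from homolog search (no qualifying speciation node)")
  }
  subfamily_scan <- NULL
  if (isTRUE(config$scan_subfamilies) && !is.null(rec)) {
    roots <- enumerate_subfamily_roots(rec, query$id, config$ancestor, tree)
    subfamily_scan <- lapply(roots, function(nd) {
      members <- leaves_under_phylo(rec$phylo, nd)
      anc <- rec$mapping[nd]
      list(mapped_ancestor = anc,
           members = sort(members),
           missing = setdiff(species_under(tree, anc),
                             unique(leaf_species(members, rec$sep))))
    })
  }
  studied <- species_under(tree, config$ancestor)
  missing <- missing_species(group, tree, config$ancestor)
  verdicts <- setNames(rep(NA_character_, length(studied)), studied)
  verdicts[intersect(group$species, studied)] <- "Present"
  group_recs <- proteome[match(intersect(group$members, proteome$id),
                               proteome$id), , drop = FALSE]

  ## Phase 2 --------------------------------------------------------------
  nucl_targets <- list()
  if (config$mode == "simple") {
    verdicts[missing] <- "Lost"
  } else {
    for (sp in missing) {
      res <- tryCatch(
        study_missing_species(sp, group_recs, tree, config, genomes,
                              annotations),
        error = function(e) list(verdict = "Unresolved",
                                 warning = conditionMessage(e)))
      verdicts[sp] <- res$verdict
      evidence[[sp]] <- res$evidence
      if (!is.null(res$warning)) warnings <- c(warnings,
                                               paste0(sp, ": ", res$warning))
      if (identical(res$verdict, "nucleotide_pending"))
        nucl_targets[[sp]] <- res
    }
  }

  ## Phase 3: rendezvous -- joint nucleotide study ------------------------
  mutation_reports <- list()
  if (length(nucl_targets)) {
    nres <- tryCatch(
      nucleotide_phase(nucl_targets, group_recs, tree, config, genomes,
                       annotations),
      error = function(e) list(error = conditionMessage(e)))
    if (!is.null(nres$error)) {
      # fall back to protein-level verdicts for the pending species
      warnings <- c(warnings, paste0("nucleotide phase fell back to protein level: ",
                                     nres$error))
      for (sp in names(nucl_targets)) {
        v <- tryCatch(
          protein_level_verdict(sp, nucl_targets[[sp]]$best_protein,
                                group_recs, tree),
          error = function(e) "Unresolved")
        verdicts[sp] <- v
      }
    } else {
      for (sp in names(nucl_targets)) {
        if (!is.null(nres$verdicts[[sp]])) {
          verdicts[sp] <- nres$verdicts[[sp]]
          mutation_reports[[sp]] <- nres$reports[[sp]]
          evidence[[sp]]$mutations <- nres$reports[[sp]]
        } else {
          verdicts[sp] <- "Unresolved"
        }
      }
      warnings <- c(warnings, nres$warnings)
    }
  }
  verdicts[is.na(verdicts)] <- "Unresolved"

  ## synthesis ------------------------------------------------------------
  ok <- verdicts != "Unresolved"
  events <- NULL
  if (any(ok)) {
    if (config$mode == "simple") {
      dl <- dollo_losses(setNames(verdicts[ok] != "Lost", names(verdicts)[ok]),
                         tree)
      events <- structure(list(
        birth = dl$birth,
        events = data.frame(branch = dl$losses,
                            event = rep("gene_loss", length(dl$losses)),
                            stringsAsFactors = FALSE),
        supporting_mutations = list()), class = "event_placements")
    } else {
      st <- sankoff_states(verdicts[ok], tree)
      events <- place_events(st, tree, mutation_reports)
    }
  }
  structure(list(query = query$id, ancestor = config$ancestor,
                 mode = config$mode, seed = config$seed,
                 verdicts = verdicts, events = events,
                 mutation_reports = mutation_reports,
                 evidence = evidence, warnings = warnings,
                 group = group, subfamily_scan = subfamily_scan),
            class = "study_report")
}

gather_homologs <- function(query, proteome, th) {
  idents <- vapply(seq_len(nrow(proteome)), function(i) {
    if (proteome$id[i] == query$id) return(100)
    global_identity(proteome$seq[i], query$seq)$identity_pct
  }, 0)
  keep <- idents >= th$homolog_min_identity_pct | proteome$id == query$id
  fam <- proteome[keep, , drop = FALSE]
  fam$identity <- idents[keep]
  fam <- fam[order(-fam$identity), , drop = FALSE]
  sel <- unlist(lapply(split(seq_len(nrow(fam)), fam$species),
                       function(ix) head(ix, th$homolog_top_n)))
  fam <- fam[sort(sel), , drop = FALSE]
  if (!query$id %in% fam$id) fam <- rbind(fam, cbind(query, identity = 100))
  rownames(fam) <- NULL
  class(fam) <- c("seq_records", "data.frame")
  fam
}

closest_reference <- function(sp, group_recs, tree) {
  cand <- group_recs[group_recs$species != sp, , drop = FALSE]
  if (!nrow(cand)) stop("no reference ortholog available")
  dv <- vapply(cand$species, function(s) divergence_time(tree, sp, s), 0)
  cand[which.min(dv), , drop = FALSE]
}

study_missing_species <- function(sp, group_recs, tree, config, genomes,
                                  annotations) {
  th <- config$thresholds
  genome <- genomes[[sp]]
  if (is.null(genome)) stop("no genome available for ", sp)
  ref <- closest_reference(sp, group_recs, tree)
  hits <- translated_search(ref$seq, genome, k = th$search_kmer,
                            score_min = th$search_score_min)
  ev <- list(reference = ref$id, n_hits = nrow(hits))
  if (nrow(hits) == 0L)
    return(list(verdict = "Lost", evidence = c(ev, list(reason = "no translated hits"))))
  cands <- chain_hits(hits, max_gap = th$chain_max_gap_nt)
  chosen <- NULL
  for (cand in head(cands, th$candidate_cap)) {
    if (candidate_is_orthologous(cand, sp, group_recs, tree, config)) {
      chosen <- cand; break
    }
  }
  if (is.null(chosen))
    return(list(verdict = "Lost",
                evidence = c(ev, list(reason = "no candidate confirmed orthologous",
                                      n_candidates = length(cands)))))
  ev$locus <- list(chrom = chosen$chrom, strand = chosen$strand,
                   span = chosen$span, score = chosen$total_score)
  locus <- extract_locus(genome, chosen, flank = th$locus_flank_nt)
  hit_prot <- gsub("*", "X", chosen$concatenated_protein, fixed = TRUE)
  pred <- predict_protein(locus, ref$seq, score_frac = th$predict_score_frac)
  ev$prediction <- if (is.null(pred)) NULL else
    list(length = nchar(pred$protein), exons = nrow(pred$exons),
         score = pred$score)
  gid <- find_annotated_gene_at_locus(annotations, sp, chosen$chrom,
                                      chosen$span, config$excluded_gene_ids)
  if (!is.null(gid))
    return(list(verdict = "Present",
                evidence = c(ev, list(annotated_gene = gid,
                                      reason = "locus already annotated; new orthology recorded"))))
  gate <- signal_gate(hit_prot, if (is.null(pred)) NULL else pred$protein,
                      ref$seq,
                      similarity_pct = th$test1_similarity_pct,
                      length_pct = th$test1_length_pct)
  ev$signal_gate <- gate
  best_prot <- if (!is.null(pred)) pred$protein else hit_prot
  if (gate == "protein_level") {
    v <- protein_level_verdict(sp, best_prot, group_recs, tree)
    return(list(verdict = v, evidence = c(ev, list(test2 = v))))
  }
  ident <- global_identity(best_prot, ref$seq)$identity_pct
  list(verdict = "nucleotide_pending", evidence = ev, locus = locus,
       best_protein = best_prot, identity = ident, reference = ref)
}

candidate_is_orthologous <- function(cand, sp, group_recs, tree, config) {
  cand_prot <- gsub("*", "X", cand$concatenated_protein, fixed = TRUE)
  if (nchar(cand_prot) < 10L) return(FALSE)
  cand_id <- paste0(sp, "|candidate")
  if (nrow(group_recs) < 2L) {
    ref <- group_recs[1L, ]
    return(global_identity(cand_prot, ref$seq)$identity_pct >=
             config$thresholds$homolog_min_identity_pct)
  }
  recs <- rbind(group_recs[, c("id", "species", "gene_id", "seq", "kind")],
                data.frame(id = cand_id, species = sp, gene_id = "candidate",
                           seq = cand_prot, kind = "protein",
                           stringsAsFactors = FALSE))
  class(recs) <- c("seq_records", "data.frame")
  d <- pairwise_distances(recs)
  rooted <- root_gene_tree(build_nj(d), tree)
  rec2 <- reconcile(rooted, tree)
  grp2 <- extract_ortholog_group(rec2, cand_id, config$ancestor, tree)
  !is.null(grp2) && any(group_recs$id %in% grp2$members)
}

protein_level_verdict <- function(sp, candidate_protein, group_recs, tree) {
  input <- select_known_pair(sp, candidate_protein, group_recs, tree)
  ct <- conservation_test(input)
  if (ct$verdict == "putative_gene") "Saved" else "Pseudogene"
}

# joint nucleotide-level study of all pending candidates
nucleotide_phase <- function(targets, group_recs, tree, config, genomes,
                             annotations) {
  th <- config$thresholds
  cand_df <- do.call(rbind, lapply(names(targets), function(sp)
    data.frame(species = sp, id = paste0(sp, "|candidate"),
               seq = targets[[sp]]$locus$seq,
               identity_pct = targets[[sp]]$identity,
               stringsAsFactors = FALSE)))
  # known loci from annotated genomes
  kn <- list()
  if (!is.null(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      spk <- annotations$species[i]
      if (spk %in% cand_df$species) next
      gid <- paste0(spk, "|", annotations$gene_id[i])
      if (!gid %in% group_recs$id) next
      g <- genomes[[spk]]
      if (is.null(g)) next
      chrom <- g[[annotations$chrom[i]]]
      exm <- annotations$exons[[i]]
      s <- max(0L, min(exm[, 1L]) - th$locus_flank_nt)
      e <- min(nchar(chrom), max(exm[, 2L]) + th$locus_flank_nt)
      seg <- substr(chrom, s + 1L, e)
      local_ex <- exm - s
      if (annotations$strand[i] == "-") {
        seg <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seg)))
        L <- e - s
        local_ex <- cbind(L - local_ex[, 2L], L - local_ex[, 1L])
        local_ex <- local_ex[rev(seq_len(nrow(local_ex))), , drop = FALSE]
      }
      prot <- group_recs$seq[match(gid, group_recs$id)]
      refp <- targets[[1L]]$reference$seq
      kn[[length(kn) + 1L]] <- list(
        row = data.frame(species = spk, id = gid, seq = seg,
                         identity_pct = global_identity(prot, refp)$identity_pct,
                         stringsAsFactors = FALSE),
        exons = local_ex)
    }
  }
  kn_df <- if (length(kn)) do.call(rbind, lapply(kn, `[[`, "row"))
           else data.frame(species = character(), id = character(),
                           seq = character(), identity_pct = numeric(),
                           stringsAsFactors = FALSE)
  set <- select_reconstruction_set(cand_df, kn_df,
                                   max_divergence_pct = th$test3_max_divergence_pct)
  # reference row: the retained annotated known closest to the targets
  kept_known <- set$species[!set$is_candidate]
  if (!length(kept_known))
    stop("no annotated reference sequence survived divergence filtering")
  mean_div <- vapply(kept_known, function(s)
    mean(vapply(cand_df$species, function(t2)
      divergence_time(tree, s, t2), 0)), 0)
  ref_sp <- kept_known[which.min(mean_div)]
  ref_exons <- kn[[which(vapply(kn, function(x) x$row$species, "") == ref_sp)]]$exons
  seqs <- setNames(set$seq, set$species)
  aln <- build_guided_alignment(seqs, ref_sp, ref_exons,
                                flank = th$compaction_flank_nt)
  guide <- prune_species_tree(tree, set$species)$phylo
  rec <- reconstruct_ancestors(aln, guide)
  scan_targets <- intersect(cand_df$species, set$species)
  reports <- scan_lineage(aln, rec, scan_targets)
  verdicts <- lapply(reports, function(r)
    if (classify_sequence(r) == "pseudogene") "Pseudogene" else "Saved")
  warn <- character(0)
  if (any(aln$low_confidence))
    warn <- sprintf("low-confidence exon projection for exon(s) %s",
                    paste(which(aln$low_confidence), collapse = ","))
  list(verdicts = verdicts, reports = reports, warnings = warn,
       alignment = aln, reconstruction = rec)
}

#' Run several independent studies
#'
#' Each element of \code{studies} is a list of arguments for
#' \code{run_study}.  Failures are isolated: a failing study yields a
#' record with an \code{error} field instead of aborting the batch.
#'
#' @param studies list of argument lists.
#' @return list of \code{study_report} or error records.
#' @export
run_batch <- function(studies) {
  lapply(studies, function(args) {
    tryCatch(do.call(run_study, args),
             error = function(e) list(error = conditionMessage(e)))
  })
}

#' @export
print.study_report <- function(x, ...) {
  cat("Lineage-loss study of", x$query, "under ancestor", x$ancestor,
      sprintf("(%s mode)\n", x$mode))
  tab <- table(factor(x$verdicts,
                      levels = c("Present", "Saved", "Pseudogene", "Lost",
                                 "Unresolved")))
  cat("Verdicts:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  if (!is.null(x$events)) {
    cat("Gene birth at:", x$events$birth, "\n")
    if (nrow(x$events$events)) {
      for (i in seq_len(nrow(x$events$events)))
        cat(sprintf("  %s on branch %s\n", x$events$events$event[i],
                    x$events$events$branch[i]))
    } else cat("  no loss or pseudogenization events\n")
  }
  if (length(x$warnings)) cat("Warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  for (sp in names(object$mutation_reports)) {
    mr <- object$mutation_reports[[sp]]
    if (is.null(mr) || !nrow(mr)) next
    cat("Mutations on the", sp, "lineage:\n")
    print(mr[, c("branch", "kind", "exon", "position", "detail")],
          row.names = FALSE)
  }
  invisible(object)
}
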