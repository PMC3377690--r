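PREFERRED_CODON <- c(
  A = "GCC", R = "CGG", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG")

back_translate <- function(protein) {
  paste(PREFERRED_CODON[strsplit(protein, "", fixed = TRUE)[[1L]]],
        collapse = "")
}

#' An illustrative ultrametric species tree of nine amniotes
#'
#' Human, chimpanzee, gorilla, orangutan, macaque, mouse, rat, dog and
#' opossum with round-number divergence times in million years; ancestor
#' codes follow the usual clade abbreviations (Hpa = Homo/Pan ancestor,
#' Hni = Homininae, Hid = Hominidae, Ctr = Catarrhini, Mur = Murinae,
#' Eth = Eutheria, The = Theria).  Times are illustrative, not a
#' calibration.
#' @return a \code{species_tree}.
#' @export
example_species_tree <- function() {
  nwk <- paste0(
    "((((((Hsa:6,Ptr:6)Hpa:9,Ggo:15)Hni:14,Ppy:29)Hid:1,Mmu:30)Ctr:60,",
    "(Mus:20,Rno:20)Mur:70)Eth:70,Mdo:160)The;")
  species_tree(ape::read.tree(text = nwk))
}

#' Assemble simulation parameters
#'
#' The defaults describe the study conditions the simulator emulates: a
#' four-exon gene (exon lengths multiples of three; introns with canonical
#' GT..AG boundaries and zero phase), a background substitution rate in
#' substitutions per site per 100 MY applied uniformly with a 2:1
#' transition:transversion ratio, and planted losses/pseudogenizations on
#' chosen branches.  Background substitutions never create or destroy
#' stops, the initiator, terminators or splice dinucleotides, so the truth
#' ledger is the deterministic consequence of the planted events.
#'
#' @param tree \code{species_tree} (default \code{example_species_tree()}).
#' @param exon_lengths nt per exon, each a multiple of 3.
#' @param intron_lengths nt per intron (length = exons - 1), each >= 30.
#' @param subst_rate substitutions/site/100 MY.
#' @param planted_events list of \code{list(branch=, kind="loss")} or
#'   \code{list(branch=, kind="pseudogenization", recipe=list(...))} where
#'   the recipe counts mutations by kind: nonsense, insertion, deletion,
#'   splice_donor, splice_acceptor, exon_loss, start_loss, stop_loss.
#' @param unannotated_species species whose intact gene is withheld from
#'   the proteome and annotations (exercises the rescue path).
#' @param intergenic_length nt of background DNA on each side of the gene.
#' @param seed integer seed.
#' @export
sim_params <- function(tree = example_species_tree(),
                       exon_lengths = c(120, 150, 90, 141),
                       intron_lengths = c(150, 200, 180),
                       subst_rate = 0.05,
                       planted_events = list(),
                       unannotated_species = character(),
                       intergenic_length = 2000,
                       seed = 1L) {
  stopifnot(all(exon_lengths %% 3 == 0), all(intron_lengths >= 30),
            length(intron_lengths) == length(exon_lengths) - 1L,
            subst_rate >= 0)
  for (ev in planted_events) {
    if (!ev$branch %in% tree$names) stop("planted branch not in tree: ", ev$branch)
    if (!ev$kind %in% c("loss", "pseudogenization")) stop("unknown event kind")
    if (ev$kind == "pseudogenization" &&
        (is.null(ev$recipe) || sum(unlist(ev$recipe)) == 0))
      stop("pseudogenization recipe must plant at least one mutation")
  }
  structure(list(tree = tree, exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 subst_rate = subst_rate, planted_events = planted_events,
                 unannotated_species = unannotated_species,
                 intergenic_length = as.integer(intergenic_length),
                 seed = as.integer(seed)),
            class = "sim_params")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

# gene-region layout in region-local coordinates (0-based half-open)
gene_layout <- function(exon_lengths, intron_lengths) {
  ne <- length(exon_lengths)
  starts <- integer(ne); ends <- integer(ne)
  pos <- 0L
  for (e in seq_len(ne)) {
    starts[e] <- pos; pos <- pos + exon_lengths[e]; ends[e] <- pos
    if (e < ne) pos <- pos + intron_lengths[e]
  }
  list(exons = cbind(starts, ends), length = pos)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

#' Simulate a gene family with planted losses and pseudogenizations
#'
#' Builds a root gene (preferred-codon back-translation of a random
#' protein, ATG start, TAA terminator, GT..AG introns), embeds it in
#' random intergenic DNA, and evolves the whole chromosome down the
#' species tree with seeded per-branch substitution counts.  On loss
#' branches the gene region is excised; on pseudogenization branches the
#' recipe's disabling mutations are applied at recorded positions (at
#' least 10 nt from exon boundaries unless a splice site is targeted) and
#' the species is withheld from the proteome.  The same seed yields
#' byte-identical outputs.
#'
#' @param params \code{sim_params}.
#' @return list of class \code{sim_family}: genomes (named list species ->
#'   named chromosome list), proteome (\code{seq_records}), annotations
#'   (\code{exon_annotations}), tree, ledger (truth: per-branch events,
#'   expected verdicts, birth node).
#' @export
simulate_family <- function(params) {
  set.seed(params$seed)
  tree <- params$tree
  lay <- gene_layout(params$exon_lengths, params$intron_lengths)
  n_aa <- sum(params$exon_lengths) / 3L - 1L   # all codons except the stop
  prot <- paste(sample(names(PREFERRED_CODON), n_aa, TRUE), collapse = "")
  prot <- paste0("M", substr(prot, 2L, n_aa))
  cds <- paste0(back_translate(prot), "TAA")
  # assemble gene region: exons from cds, introns GT..AG
  exseq <- character(length(params$exon_lengths))
  pos <- 0L
  for (e in seq_along(exseq)) {
    exseq[e] <- substr(cds, pos + 1L, pos + params$exon_lengths[e])
    pos <- pos + params$exon_lengths[e]
  }
  inseq <- vapply(params$intron_lengths, function(L)
    paste0("GT", rand_dna(L - 4L), "AG"), "")
  gene <- paste0(paste0(exseq, c(inseq, "")), collapse = "")
  left <- rand_dna(params$intergenic_length)
  right <- rand_dna(params$intergenic_length)
  root_chrom <- paste0(left, gene, right)
  gene_start <- nchar(left)
  exons_chrom <- lay$exons + gene_start
  # per-branch planted events
  planted <- list()
  for (ev in params$planted_events) planted[[ev$branch]] <- ev
  # evolve down the tree; state per node: chromosome string, has_gene,
  # pseudogenized, protected positions (chromosome coords, 0-based)
  phy <- tree$phylo
  nn <- tree$n_tip + phy$Nnode
  node_state <- vector("list", nn)
  root <- tree$n_tip + 1L
  node_state[[root]] <- list(chrom = root_chrom, has_gene = TRUE,
                             pseudo = FALSE, protected = integer(0),
                             exons = exons_chrom)
  ledger_events <- list()
  for (k in reorder_edges_preorder(phy)) {
    par <- phy$edge[k, 1L]; ch <- phy$edge[k, 2L]
    st <- node_state[[par]]
    blen <- phy$edge.length[k]
    chname <- tree$names[ch]
    if (st$has_gene && !is.null(planted[[chname]])) {
      ev <- planted[[chname]]
      if (ev$kind == "loss") {
        st <- excise_gene(st)
        ledger_events[[chname]] <- list(branch = chname, kind = "loss",
                                        mutations = empty_mutations())
      } else {
        res <- apply_recipe(st, ev$recipe, params)
        st <- res$state
        st$pseudo <- TRUE
        ledger_events[[chname]] <- list(branch = chname,
                                        kind = "pseudogenization",
                                        mutations = res$mutations)
      }
    }
    st <- substitute_branch(st, blen, params$subst_rate)
    node_state[[ch]] <- st
  }
  # outputs
  genomes <- list(); prot_rows <- list(); ann <- list()
  verdict <- character(0)
  for (i in seq_len(tree$n_tip)) {
    sp <- tree$names[i]
    st <- node_state[[i]]
    genomes[[sp]] <- list(chr1 = st$chrom)
    if (!st$has_gene) { verdict[sp] <- "Lost"; next }
    if (st$pseudo) { verdict[sp] <- "Pseudogene"; next }
    p <- translate_exons(st)
    if (sp %in% params$unannotated_species) {
      verdict[sp] <- "Saved"
      next
    }
    verdict[sp] <- "Present"
    gid <- paste0(sp, "|g1")
    prot_rows[[sp]] <- data.frame(id = gid, species = sp, gene_id = "g1",
                                  seq = p, kind = "protein",
                                  stringsAsFactors = FALSE)
    ann[[sp]] <- list(gene_id = "g1", species = sp, chrom = "chr1",
                      strand = "+", exons = st$exons)
  }
  proteome <- do.call(rbind, prot_rows)
  if (!is.null(proteome)) class(proteome) <- c("seq_records", "data.frame")
  annotations <- if (length(ann))
    exon_annotations(gene_id = vapply(ann, `[[`, "", "gene_id"),
                     species = vapply(ann, `[[`, "", "species"),
                     chrom = vapply(ann, `[[`, "", "chrom"),
                     strand = vapply(ann, `[[`, "", "strand"),
                     exons = lapply(ann, `[[`, "exons"))
  else NULL
  ledger <- structure(list(events = ledger_events,
                           verdicts = verdict,
                           birth = tree$names[root],
                           exon_lengths = params$exon_lengths,
                           root_protein = paste0(prot)),
                      class = "truth_ledger")
  structure(list(genomes = genomes, proteome = proteome,
                 annotations = annotations, tree = tree,
                 ledger = ledger, params = params),
            class = "sim_family")
}

excise_gene <- function(st) {
  gs <- st$exons[1L, 1L]
  ge <- st$exons[nrow(st$exons), 2L]
  st$chrom <- paste0(substr(st$chrom, 1L, gs),
                     substr(st$chrom, ge + 1L, nchar(st$chrom)))
  st$has_gene <- FALSE
  st$exons <- NULL
  st
}

translate_exons <- function(st) {
  cds <- paste(substring(st$chrom, st$exons[, 1L] + 1L, st$exons[, 2L]),
               collapse = "")
  aa <- translate_dna(cds)
  sub("\\*$", "", aa)
}

# uniform background substitutions that never flip gene-critical positions
substitute_branch <- function(st, blen, rate) {
  L <- nchar(st$chrom)
  n_sub <- rbinom(1L, L, min(1, rate * blen / 100))
  if (n_sub == 0L) return(st)
  chars <- strsplit(st$chrom, "", fixed = TRUE)[[1L]]
  pos <- sample.int(L, n_sub)
  for (p in pos) {
    if ((p - 1L) %in% st$protected) next
    old <- chars[p]
    if (!old %in% c("A", "C", "G", "T")) next
    new <- if (runif(1L) < 2 / 3) TRANSITION[[old]]
           else sample(TRANSVERSIONS[[old]], 1L)
    if (st$has_gene && !st$pseudo && !is.null(st$exons) &&
        breaks_gene(chars, p, new, st$exons)) next
    chars[p] <- new
  }
  st$chrom <- paste(chars, collapse = "")
  st
}

# would substituting position p (1-based) with `new` disable the gene?
breaks_gene <- function(chars, p, new, exons) {
  ne <- nrow(exons)
  # splice dinucleotides: 2 nt after each exon end, 2 nt before each start
  for (e in seq_len(ne - 1L)) {
    if (p > exons[e, 2L] && p <= exons[e, 2L] + 2L) return(TRUE)
    if (p > exons[e + 1L, 1L] - 2L && p <= exons[e + 1L, 1L]) return(TRUE)
  }
  # inside an exon?
  for (e in seq_len(ne)) {
    if (p > exons[e, 1L] && p <= exons[e, 2L]) {
      # start codon and terminator are protected
      if (e == 1L && p <= exons[1L, 1L] + 3L) return(TRUE)
      if (e == ne && p > exons[ne, 2L] - 3L) return(TRUE)
      # codon position within CDS (phase-0 exons assumed)
      off <- cds_offset(p, exons)
      cstart_off <- (off %/% 3L) * 3L
      codon_pos <- cds_positions(cstart_off, exons)
      cod <- chars[codon_pos]
      cod[(off %% 3L) + 1L] <- new
      if (paste(cod, collapse = "") %in% STOP_CODONS) return(TRUE)
      return(FALSE)
    }
  }
  FALSE
}

# 0-based CDS offset of chromosome position p (1-based) given exon matrix
cds_offset <- function(p, exons) {
  off <- 0L
  for (e in seq_len(nrow(exons))) {
    if (p > exons[e, 1L] && p <= exons[e, 2L])
      return(off + (p - 1L - exons[e, 1L]))
    off <- off + (exons[e, 2L] - exons[e, 1L])
  }
  stop("position not in CDS")
}

# chromosome positions (1-based) of the 3 CDS offsets starting at cstart_off
cds_positions <- function(cstart_off, exons) {
  offs <- cstart_off + 0:2
  out <- integer(3L)
  for (i in 1:3) {
    off <- offs[i]; acc <- 0L
    for (e in seq_len(nrow(exons))) {
      len <- exons[e, 2L] - exons[e, 1L]
      if (off < acc + len) { out[i] <- exons[e, 1L] + (off - acc) + 1L; break }
      acc <- acc + len
    }
  }
  out
}

# apply a pseudogenization recipe; returns updated state + mutation table
apply_recipe <- function(st, recipe, params) {
  muts <- list()
  exons <- st$exons
  ne <- nrow(exons)
  chars <- strsplit(st$chrom, "", fixed = TRUE)[[1L]]
  protected <- st$protected
  used_exons <- integer(0)
  # helper to rebuild string at the end; indels handled via chars list ops
  note <- function(kind, exon, position, detail = "", len = NA_integer_) {
    muts[[length(muts) + 1L]] <<- data.frame(kind = kind, exon = exon,
      position = as.integer(position), detail = detail,
      length = as.integer(len), stringsAsFactors = FALSE)
  }
  count <- function(key) if (is.null(recipe[[key]])) 0L else as.integer(recipe[[key]])
  # interior codon slots per exon, >= 12 nt away from boundaries and away
  # from start/stop codons
  pick_codon <- function(exon) {
    len <- exons[exon, 2L] - exons[exon, 1L]
    nc <- len %/% 3L
    lo <- 5L; hi <- nc - 4L
    if (exon == 1L) lo <- max(lo, 3L)
    if (hi < lo) stop("exon too short for planted mutation")
    sample(lo:hi, 1L)
  }
  for (i in seq_len(count("nonsense"))) {
    # deterministic seeded retry on position collisions
    for (try in 1:100) {
      exon <- sample(seq_len(ne), 1L)
      cod <- pick_codon(exon)
      p0 <- exons[exon, 1L] + 3L * (cod - 1L)
      if (!any((p0 + 0:2) %in% protected)) break
    }
    # phase-0 exons: codon cod occupies exon-local nt 3(cod-1)+1 .. 3cod
    stopifnot(cds_phase_at_exon(exon, exons) == 0L)
    chars[(p0 + 1L):(p0 + 3L)] <- c("T", "A", "A")
    protected <- c(protected, p0 + 0:2)
    note("nonsense", exon, cod, "TAA")
  }
  for (i in seq_len(count("start_loss"))) {
    p0 <- exons[1L, 1L]
    chars[(p0 + 1L):(p0 + 3L)] <- c("A", "T", "A")
    protected <- c(protected, p0 + 0:2)
    note("start_loss", 1L, 1L, "ATA")
  }
  for (i in seq_len(count("stop_loss"))) {
    p0 <- exons[ne, 2L] - 3L
    chars[(p0 + 1L):(p0 + 3L)] <- c("C", "A", "A")
    protected <- c(protected, p0 + 0:2)
    note("stop_loss", ne, (exons[ne, 2L] - exons[ne, 1L]) %/% 3L, "CAA")
  }
  donor_free <- seq_len(ne - 1L)
  for (i in seq_len(min(count("splice_donor"), ne - 1L))) {
    j <- if (length(donor_free) == 1L) donor_free else sample(donor_free, 1L)
    donor_free <- setdiff(donor_free, j)
    p0 <- exons[j, 2L] + 1L                    # the T of GT, 0-based
    chars[p0 + 1L] <- "C"                      # GT -> GC
    protected <- c(protected, p0)
    note("splice_donor", j, 1L, "GC")
  }
  acc_free <- seq_len(ne - 1L)
  for (i in seq_len(min(count("splice_acceptor"), ne - 1L))) {
    j <- if (length(acc_free) == 1L) acc_free else sample(acc_free, 1L)
    acc_free <- setdiff(acc_free, j)
    p0 <- exons[j + 1L, 1L] - 2L               # the A of AG, 0-based
    chars[p0 + 1L] <- "C"                      # AG -> CG
    protected <- c(protected, p0)
    note("splice_acceptor", j, 1L, "CG")
  }
  # indels and exon loss change coordinates: apply from the 3' end so earlier
  # coordinates stay valid, at most one structural edit per exon
  struct <- list()
  for (i in seq_len(count("exon_loss"))) struct[[length(struct) + 1L]] <- "exon_loss"
  for (i in seq_len(count("insertion"))) struct[[length(struct) + 1L]] <- "insertion"
  for (i in seq_len(count("deletion"))) struct[[length(struct) + 1L]] <- "deletion"
  if (length(struct)) {
    used <- integer(0)
    plans <- list()
    for (kind in struct) {
      avail <- setdiff(if (kind == "exon_loss") setdiff(seq_len(ne), c(1L, ne))
                       else seq_len(ne), used)
      if (!length(avail)) stop("not enough exons for structural recipe")
      exon <- if (length(avail) == 1L) avail else sample(avail, 1L)
      used <- c(used, exon)
      len <- if (kind == "insertion") sample(c(1L, 2L, 4L, 5L, 7L), 1L)
             else if (kind == "deletion") sample(c(1L, 2L, 4L, 5L), 1L)
             else NA_integer_
      elen <- exons[exon, 2L] - exons[exon, 1L]
      off <- if (kind == "exon_loss") NA_integer_
             else sample(seq(13L, elen - 12L - max(len, 0L)), 1L)
      plans[[length(plans) + 1L]] <- list(kind = kind, exon = exon,
                                          off = off, len = len)
    }
    ord <- order(-vapply(plans, `[[`, 0L, "exon"))
    # canonical indel position: shift left while the residue before the
    # block equals the block's last residue (left alignment)
    left_align <- function(v, at, len, floor_) {
      while (at > floor_ && v[at] == v[at + len]) at <- at - 1L
      at
    }
    for (pl in plans[ord]) {
      if (pl$kind == "insertion") {
        at <- exons[pl$exon, 1L] + pl$off       # insert after this many nt
        ins <- sample(c("A", "C", "G", "T"), pl$len, TRUE)
        chars <- append(chars, ins, after = at)
        canon <- left_align(chars, at, pl$len, exons[pl$exon, 1L]) -
                 exons[pl$exon, 1L]
        shift <- pl$len
        sel <- exons[, 1L] >= at; exons[sel, 1L] <- exons[sel, 1L] + shift
        sel <- exons[, 2L] > at; exons[sel, 2L] <- exons[sel, 2L] + shift
        protected <- c(protected + ifelse(protected >= at, shift, 0L),
                       at + 0:(shift - 1L))
        note("insertion", pl$exon, canon + 1L, "", pl$len)
        if (pl$len %% 3L != 0L)
          note("frameshift", pl$exon, canon + 1L,
               sprintf("insertion of %d nt", pl$len), pl$len)
      } else if (pl$kind == "deletion") {
        at <- exons[pl$exon, 1L] + pl$off
        canon <- left_align(chars, at, pl$len, exons[pl$exon, 1L]) -
                 exons[pl$exon, 1L]
        chars <- chars[-((at + 1L):(at + pl$len))]
        shift <- pl$len
        protected <- protected[!(protected >= at & protected < at + shift)]
        protected <- protected - ifelse(protected >= at + shift, shift, 0L)
        sel <- exons[, 1L] > at; exons[sel, 1L] <- exons[sel, 1L] - shift
        sel <- exons[, 2L] > at; exons[sel, 2L] <- exons[sel, 2L] - shift
        note("deletion", pl$exon, canon + 1L, "", pl$len)
        if (pl$len %% 3L != 0L)
          note("frameshift", pl$exon, canon + 1L,
               sprintf("deletion of %d nt", pl$len), pl$len)
      } else {  # exon_loss: delete the exon body
        at <- exons[pl$exon, 1L]
        len <- exons[pl$exon, 2L] - exons[pl$exon, 1L]
        chars <- chars[-((at + 1L):(at + len))]
        protected <- protected[!(protected >= at & protected < at + len)]
        protected <- protected - ifelse(protected >= at + len, len, 0L)
        sel <- exons[, 1L] > at; exons[sel, 1L] <- exons[sel, 1L] - len
        sel <- exons[, 2L] > at; exons[sel, 2L] <- exons[sel, 2L] - len
        exons[pl$exon, 2L] <- exons[pl$exon, 1L]   # empty interval marker
        note("exon_loss", pl$exon, 1L, "")
      }
    }
  }
  st$chrom <- paste(chars, collapse = "")
  st$exons <- exons
  st$protected <- unique(protected)
  res_m <- if (length(muts)) do.call(rbind, muts) else empty_mutations()
  # an exon loss physically erases any point mutation planted in that exon,
  # and silences the splice junctions flanking it
  lost_ex <- res_m$exon[res_m$kind == "exon_loss"]
  if (length(lost_ex)) {
    res_m <- res_m[res_m$kind == "exon_loss" | !(res_m$exon %in% lost_ex), ,
                   drop = FALSE]
    is_splice <- res_m$kind %in% c("splice_donor", "splice_acceptor")
    adj <- res_m$exon %in% c(lost_ex, lost_ex - 1L)
    res_m <- res_m[!(is_splice & adj), , drop = FALSE]
  }
  rownames(res_m) <- NULL
  list(state = st, mutations = res_m)
}

cds_phase_at_exon <- function(exon, exons) {
  if (exon == 1L) return(0L)
  sum(exons[seq_len(exon - 1L), 2L] - exons[seq_len(exon - 1L), 1L]) %% 3L
}

#' Expected study report implied by a truth ledger
#'
#' @param ledger \code{truth_ledger} from \code{simulate_family}.
#' @return list with \code{verdicts}, \code{events} data.frame (branch,
#'   event), \code{mutations} (per branch), \code{birth}.
#' @export
expected_report <- function(ledger) {
  evs <- ledger$events
  events <- if (length(evs))
    data.frame(branch = vapply(evs, `[[`, "", "branch"),
               event = ifelse(vapply(evs, `[[`, "", "kind") == "loss",
                              "gene_loss", "pseudogenization"),
               stringsAsFactors = FALSE)
  else data.frame(branch = character(), event = character(),
                  stringsAsFactors = FALSE)
  rownames(events) <- NULL
  list(verdicts = ledger$verdicts,
       events = events,
       mutations = lapply(evs, `[[`, "mutations"),
       birth = ledger$birth)
}

#' Draw a random study scenario
#'
#' Deterministically samples a scenario from the study conditions the
#' simulator emulates: zero or more planted events (a gene loss and/or a
#' pseudogenization with a 1-3 mutation recipe) on non-nested branches of
#' the example tree, optionally an unannotated species exercising the
#' rescue path.  The query species (the opossum outgroup) is never
#' touched, so every scenario remains analysable from the same query.
#'
#' @param seed integer scenario seed.
#' @param subst_rate background substitution rate (/site/100 MY).
#' @param kinds which planted event kinds to allow.
#' @return a \code{sim_params} object.
#' @export
random_scenario <- function(seed, subst_rate = 0.03,
                            kinds = c("loss", "pseudogenization", "saved")) {
  set.seed(seed)
  tree <- example_species_tree()
  pool <- c("Hsa", "Ptr", "Ggo", "Ppy", "Mmu", "Mus", "Rno",
            "Hpa", "Hni", "Mur")
  events <- list()
  used <- character(0)
  blocked <- character(0)
  take_branch <- function() {
    avail <- setdiff(pool, blocked)
    if (!length(avail)) return(NULL)
    sample(avail, 1L)
  }
  block <- function(b) {
    # a used branch, everything under it, and its ancestors are off limits
    under <- if (is_leaf(tree, b)) b else descendant_names(tree, b)
    path <- branch_path(tree, "The", b)
    unique(c(blocked, under, path))
  }
  recipe_pool <- c("nonsense", "deletion", "insertion",
                   "splice_donor", "splice_acceptor")
  if ("pseudogenization" %in% kinds) {
    b <- take_branch()
    if (!is.null(b)) {
      nmut <- sample(1:3, 1L)
      picks <- sample(recipe_pool, nmut, replace = TRUE)
      recipe <- as.list(table(picks))
      events[[length(events) + 1L]] <-
        list(branch = b, kind = "pseudogenization", recipe = recipe)
      blocked <- block(b); used <- c(used, b)
    }
  }
  if ("loss" %in% kinds && runif(1L) < 0.7) {
    b <- take_branch()
    if (!is.null(b)) {
      events[[length(events) + 1L]] <- list(branch = b, kind = "loss")
      blocked <- block(b); used <- c(used, b)
    }
  }
  unann <- character(0)
  if ("saved" %in% kinds && runif(1L) < 0.5) {
    leaves <- setdiff(c("Hsa", "Ptr", "Ggo", "Ppy", "Mmu", "Mus", "Rno"),
                      blocked)
    if (length(leaves)) unann <- sample(leaves, 1L)
  }
  sim_params(tree = tree, subst_rate = subst_rate, planted_events = events,
             unannotated_species = unann, seed = seed)
}
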