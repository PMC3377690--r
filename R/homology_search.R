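#' Six-frame translation of a nucleotide sequence
#'
#' Frames \code{+0,+1,+2} read the plus strand at offsets 0..2; frames
#' \code{-0,-1,-2} read the reverse complement at the same offsets.  Stop
#' codons are rendered \code{*}; codons containing \code{N} become \code{X}.
#'
#' @param dna nucleotide string (ACGTN).
#' @return named character vector of the 6 translations
#'   (\code{"+0".."-2"}).
#' @export
six_frame_translate <- function(dna) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  out <- character(6)
  nms <- c("+0", "+1", "+2", "-0", "-1", "-2")
  for (i in 0:2) {
    out[i + 1L] <- translate_dna(substring(dna, i + 1L))
    out[i + 4L] <- translate_dna(substring(rc, i + 1L))
  }
  names(out) <- nms
  out
}

translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  s <- substr(dna, 1L, n * 3L)
  aa <- Biostrings::translate(Biostrings::DNAString(s),
                              if.fuzzy.codon = "X", no.init.codon = TRUE)
  as.character(aa)
}

#' Seed-and-extend translated search of a genome with a protein query
#'
#' A self-contained functional equivalent of a translated nucleotide search:
#' exact protein k-mer seeds (default k = 4) are matched against all six
#' reading frames of every chromosome, seeds are grouped by diagonal, and
#' each group is extended by local affine-gap alignment (BLOSUM62, gap open
#' 11, extend 1) of the query against a window of the frame translation.
#' Stop codons in a frame score as strong mismatches but do not terminate
#' the extension.  Hits at or above \code{score_min} are reported with
#' plus-strand genome coordinates, sorted by descending score.
#'
#' @param reference protein \code{seq_records} row or a protein string.
#' @param genome named list (or \code{seq_records}) of chromosome DNA
#'   strings.
#' @param k seed k-mer length.
#' @param score_min minimum reported alignment score (matrix units).
#' @param gap_open,gap_ext affine gap penalties.
#' @return data.frame of class \code{translated_hits}: chrom, strand, frame,
#'   genome_start/genome_end (0-based half-open, plus strand),
#'   protein_start/protein_end (1-based inclusive), score, hit_protein (the
#'   aligned frame translation, gaps removed).
#' @export
translated_search <- function(reference, genome, k = 4L, score_min = 50,
                              gap_open = 11, gap_ext = 1) {
  prot <- if (is.character(reference)) reference else reference$seq[1L]
  if (nchar(prot) < k) stop("reference shorter than seed size")
  chroms <- as_chrom_list(genome)
  sub <- blosum62()
  ref_kmers <- substring(prot, seq_len(nchar(prot) - k + 1L),
                         seq_len(nchar(prot) - k + 1L) + k - 1L)
  hits <- list()
  for (chrom in names(chroms)) {
    dna <- chroms[[chrom]]
    frames <- six_frame_translate(dna)
    n <- nchar(dna)
    for (fr in names(frames)) {
      faa <- frames[[fr]]
      flen <- nchar(faa)
      if (flen < k) next
      fk <- substring(faa, seq_len(flen - k + 1L), seq_len(flen - k + 1L) + k - 1L)
      mt <- match(fk, ref_kmers)
      pos <- which(!is.na(mt))
      if (!length(pos)) next
      diag <- pos - mt[pos]          # frame_pos - query_pos
      # cluster seeds on nearby diagonals
      o <- order(diag, pos)
      pos <- pos[o]; diag <- diag[o]
      grp <- cumsum(c(1L, abs(diff(diag)) > 10L | diff(pos) > nchar(prot) + 50L))
      for (g in unique(grp)) {
        sel <- grp == g
        d0 <- diag[sel][1L]
        lo <- max(1L, min(pos[sel]) - nchar(prot) %/% 2L - 10L)
        hi <- min(flen, max(pos[sel]) + nchar(prot) + 10L)
        window <- substr(faa, lo, hi)
        al <- .sw_align_cpp(prot, window, sub, gap_open, gap_ext)
        if (al$score < score_min) next
        f_start <- lo + al$b_start - 1L   # 1-based frame aa coords
        f_end <- lo + al$b_end - 1L
        off <- as.integer(substr(fr, 2L, 2L))
        if (substr(fr, 1L, 1L) == "+") {
          gs <- off + 3L * (f_start - 1L)       # 0-based
          ge <- off + 3L * f_end
        } else {
          # coordinates on reverse complement, mapped back to plus strand
          rs <- off + 3L * (f_start - 1L)
          re <- off + 3L * f_end
          gs <- n - re
          ge <- n - rs
        }
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom,
          strand = substr(fr, 1L, 1L),
          frame = off,
          genome_start = gs, genome_end = ge,
          protein_start = al$a_start, protein_end = al$a_end,
          score = al$score,
          hit_protein = gsub("-", "", al$b, fixed = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    out <- data.frame(chrom = character(), strand = character(),
                      frame = integer(), genome_start = integer(),
                      genome_end = integer(), protein_start = integer(),
                      protein_end = integer(), score = numeric(),
                      hit_protein = character(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, hits)
    # deduplicate overlapping hits from adjacent seed groups: keep best per
    # (chrom, strand, overlapping genome span)
    out <- out[order(-out$score, out$chrom, out$genome_start), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1L]) {
      for (j in which(keep[seq_len(i - 1L)])) {
        if (out$chrom[i] == out$chrom[j] && out$strand[i] == out$strand[j] &&
            out$genome_start[i] < out$genome_end[j] &&
            out$genome_end[i] > out$genome_start[j]) {
          keep[i] <- FALSE; break
        }
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("translated_hits", "data.frame")
  out
}

as_chrom_list <- function(genome) {
  if (inherits(genome, "seq_records") || is.data.frame(genome)) {
    setNames(as.list(genome$seq), genome$id)
  } else if (is.list(genome)) {
    genome
  } else if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    as.list(genome)
  } else stop("unsupported genome container")
}

#' Chain compatible translated hits into locus candidates
#'
#' Greedy chaining in descending score order: a hit joins a chain when it is
#' on the same chromosome and strand, collinear with the chain in both
#' genome and protein coordinates (transcript orientation), within
#' \code{max_gap} nt of the chain's nearest hit, and overlaps the chain's
#' protein coverage by at most \code{max_protein_overlap} residues.  Each
#' hit belongs to exactly one candidate; candidates are sorted by descending
#' total score.
#'
#' @param hits \code{translated_hits}.
#' @param max_gap maximum genomic gap between consecutive hits (nt).
#' @param max_protein_overlap tolerated protein-coverage overlap (aa).
#' @return list of \code{locus_candidate} objects (hits data.frame,
#'   total_score, chrom, strand, span).
#' @export
chain_hits <- function(hits, max_gap = 50000, max_protein_overlap = 5) {
  if (nrow(hits) == 0L) return(list())
  hits <- hits[order(-hits$score), , drop = FALSE]
  assigned <- rep(FALSE, nrow(hits))
  cands <- list()
  for (i in seq_len(nrow(hits))) {
    if (assigned[i]) next
    chain <- i; assigned[i] <- TRUE
    repeat {
      added <- FALSE
      for (j in seq_len(nrow(hits))) {
        if (assigned[j]) next
        if (chain_compatible(hits, chain, j, max_gap, max_protein_overlap)) {
          chain <- c(chain, j); assigned[j] <- TRUE; added <- TRUE
        }
      }
      if (!added) break
    }
    ch <- hits[chain, , drop = FALSE]
    # transcript order: ascending genome for +, descending for -
    ch <- ch[order(if (ch$strand[1L] == "+") ch$genome_start
                   else -ch$genome_start), , drop = FALSE]
    cands[[length(cands) + 1L]] <- structure(
      list(hits = ch,
           total_score = sum(ch$score),
           chrom = ch$chrom[1L], strand = ch$strand[1L],
           span = c(min(ch$genome_start), max(ch$genome_end)),
           concatenated_protein = paste(ch$hit_protein, collapse = "")),
      class = "locus_candidate")
  }
  ord <- order(-vapply(cands, `[[`, 0, "total_score"))
  cands[ord]
}

chain_compatible <- function(hits, chain, j, max_gap, max_overlap) {
  ch <- hits[chain, , drop = FALSE]
  hj <- hits[j, , drop = FALSE]
  if (hj$chrom != ch$chrom[1L] || hj$strand != ch$strand[1L]) return(FALSE)
  # genomic disjointness and gap
  if (any(hj$genome_start < ch$genome_end & hj$genome_end > ch$genome_start))
    return(FALSE)
  gap <- min(abs(c(hj$genome_start - ch$genome_end,
                   ch$genome_start - hj$genome_end)))
  if (gap > max_gap) return(FALSE)
  # protein overlap
  ov <- pmin(hj$protein_end, ch$protein_end) -
        pmax(hj$protein_start, ch$protein_start) + 1L
  if (any(ov > max_overlap)) return(FALSE)
  # collinearity: genome order must match protein order in transcript sense
  for (r in seq_len(nrow(ch))) {
    genome_after <- hj$genome_start >= ch$genome_end[r]
    if (hj$strand == "-") genome_after <- !genome_after
    protein_after <- hj$protein_start >= ch$protein_start[r]
    if (genome_after != protein_after) return(FALSE)
  }
  TRUE
}

#' Extract the DNA locus around a chained candidate
#'
#' Takes the plus-strand substring from the first hit start minus
#' \code{flank} to the last hit end plus \code{flank}, clamped to the
#' chromosome; minus-strand candidates are reverse-complemented so the locus
#' reads in transcript orientation.  The recorded offset maps locus-local
#' coordinates back to the plus strand.
#'
#' @param genome chromosome container as in \code{translated_search}.
#' @param candidate \code{locus_candidate}.
#' @param flank nt of flank on each side.
#' @return list of class \code{locus_dna}: seq, chrom, strand, offset
#'   (0-based plus-strand start of the extracted window) and window end.
#' @export
extract_locus <- function(genome, candidate, flank = 5000) {
  chroms <- as_chrom_list(genome)
  dna <- chroms[[candidate$chrom]]
  n <- nchar(dna)
  s <- max(0L, candidate$span[1L] - as.integer(flank))
  e <- min(n, candidate$span[2L] + as.integer(flank))
  seg <- substr(dna, s + 1L, e)
  if (candidate$strand == "-")
    seg <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  structure(list(seq = seg, chrom = candidate$chrom,
                 strand = candidate$strand, offset = s, end = e),
            class = "locus_dna")
}

#' Map a locus-local interval back to plus-strand genome coordinates
#' @param locus \code{locus_dna}.
#' @param start,end 0-based half-open local interval.
#' @return c(start, end) on the plus strand, 0-based half-open.
#' @export
locus_to_genome <- function(locus, start, end) {
  if (locus$strand == "+") {
    c(locus$offset + start, locus$offset + end)
  } else {
    c(locus$end - end, locus$end - start)
  }
}
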