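#' Predict the protein most similar to a reference from a DNA locus
#'
#' A spliced-alignment dynamic program aligns the reference protein against
#' the locus.  Introns may be entered only at codon boundaries, must start
#' with GT, end with AG and span at least \code{min_intron} nt; codons
#' translating to a stop are excluded from exons, so the optimal prediction
#' must shorten, splice around or frame-shift past any nonsense codon.  A
#' start codon is not required: degraded pseudogene loci still need a best
#' protein for downstream testing.  Returns NULL when the best score falls
#' below \code{score_frac} times the reference self-score.
#'
#' @param locus a \code{locus_dna} (or plain DNA string).
#' @param reference reference protein string.
#' @param gap_open,gap_ext affine penalties within exons.
#' @param intron_open fixed penalty per intron.
#' @param min_intron minimum intron length (nt).
#' @param score_frac acceptance threshold as a fraction of the reference
#'   self-alignment score.
#' @return list of class \code{protein_prediction}: protein, exons (0-based
#'   half-open locus-local intervals), splice_sites (donor/acceptor
#'   dinucleotides per junction), score, frame_per_exon; or NULL.
#' @export
predict_protein <- function(locus, reference, gap_open = 10, gap_ext = 0.5,
                            intron_open = 20, min_intron = 20,
                            score_frac = 0.4) {
  dna <- if (is.character(locus)) locus else locus$seq
  if (nchar(dna) < 3L) stop("locus shorter than one codon")
  sub <- blosum62()
  res <- .spliced_align_cpp(reference, dna, sub, gap_open, gap_ext,
                            intron_open, as.integer(min_intron))
  if (length(res) == 1L) return(NULL)
  self <- sum(vapply(strsplit(reference, "", fixed = TRUE)[[1L]],
                     function(a) sub[a, a], 0))
  if (res$score < score_frac * self) return(NULL)
  ex <- res$exons
  splice <- NULL
  if (nrow(ex) > 1L) {
    splice <- data.frame(
      donor = substr(dna, ex[-nrow(ex), 2L] + 1L, ex[-nrow(ex), 2L] + 2L),
      acceptor = substr(dna, ex[-1L, 1L] - 1L, ex[-1L, 1L]),
      stringsAsFactors = FALSE)
  }
  structure(list(protein = res$protein,
                 exons = ex,
                 splice_sites = splice,
                 score = res$score,
                 self_score = self,
                 prot_range = c(res$prot_start, res$prot_end),
                 frame_per_exon = ex[, 1L] %% 3L,
                 aligned_ref = res$aligned_ref,
                 aligned_pred = res$aligned_pred),
            class = "protein_prediction")
}

#' @export
print.protein_prediction <- function(x, ...) {
  cat("Protein prediction:", nchar(x$protein), "aa,", nrow(x$exons),
      "exon(s), score", round(x$score, 1), "\n")
  invisible(x)
}

#' Find an already-annotated gene overlapping a genomic interval
#'
#' Screens the annotation set for a gene of the given species whose exon
#' span overlaps the query interval by at least one nucleotide; the gene
#' with the largest overlap wins.  Genes in \code{excluded} are ignored,
#' which is how suspicious annotations are re-annotated by relaunching a
#' study without them.
#'
#' @param annotations \code{exon_annotations}.
#' @param species species code.
#' @param chrom chromosome name.
#' @param interval c(start, end), 0-based half-open plus-strand.
#' @param excluded character vector of gene ids to ignore.
#' @return the gene_id, or NULL.
#' @export
find_annotated_gene_at_locus <- function(annotations, species, chrom,
                                         interval, excluded = character()) {
  if (is.null(annotations) || nrow(annotations) == 0L) return(NULL)
  sel <- annotations$species == species & annotations$chrom == chrom &
         !(annotations$gene_id %in% excluded)
  if (!any(sel)) return(NULL)
  ann <- annotations[sel, , drop = FALSE]
  ov <- vapply(ann$exons, function(m) {
    spans <- pmin(m[, 2L], interval[2L]) - pmax(m[, 1L], interval[1L])
    sum(pmax(spans, 0L))
  }, 0L)
  if (max(ov) < 1L) return(NULL)
  ann$gene_id[which.max(ov)]
}
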