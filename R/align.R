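#' Global protein alignment with affine gaps
#'
#' Needleman-Wunsch with BLOSUM62 scoring, affine gap penalties (a gap run of
#' length L costs \code{gap_open + L * gap_ext}) and penalised end gaps.
#' Traceback ties are resolved in the fixed order diagonal > up > left so
#' alignments are bit-reproducible.
#'
#' @param a,b residue strings.
#' @param sub substitution matrix (default BLOSUM62).
#' @param gap_open,gap_ext gap penalties.
#' @param free_end_gaps if TRUE, leading/trailing gaps are free.
#' @return list with \code{score} and gapped strings \code{a}, \code{b}.
#' @export
nw_align <- function(a, b, sub = blosum62(), gap_open = 10, gap_ext = 0.5,
                     free_end_gaps = FALSE) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  .nw_align_cpp(a, b, sub, gap_open, gap_ext, free_end_gaps)
}

#' Percent identity and length ratio between a candidate and a reference
#'
#' Identity is the percentage of identical columns over the full global
#' alignment length, gap columns included; the length ratio is
#' \code{100 * nchar(candidate) / nchar(reference)}.  Counting gap columns in
#' the denominator penalises truncated pseudogene fragments.
#'
#' @param candidate,reference protein strings (candidate first).
#' @param gap_open,gap_ext affine gap penalties.
#' @return list of class \code{similarity_result}: \code{identity_pct},
#'   \code{length_ratio_pct}, \code{score}, \code{alignment} (two gapped
#'   strings).
#' @export
global_identity <- function(candidate, reference, gap_open = 10,
                            gap_ext = 0.5) {
  al <- nw_align(candidate, reference, gap_open = gap_open, gap_ext = gap_ext)
  ca <- strsplit(al$a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al$b, "", fixed = TRUE)[[1L]]
  ident <- 100 * sum(ca == cb & ca != "-") / length(ca)
  structure(list(identity_pct = ident,
                 length_ratio_pct = 100 * nchar(candidate) / nchar(reference),
                 score = al$score,
                 alignment = c(al$a, al$b)),
            class = "similarity_result")
}

# p-distance over mutually ungapped columns of a pairwise global alignment,
# transformed as -ln(1 - p); distances with p >= cap_p are capped.
protein_distance <- function(a, b, cap_p = 0.95, cap_value = 5) {
  al <- nw_align(a, b)
  ca <- strsplit(al$a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al$b, "", fixed = TRUE)[[1L]]
  keep <- ca != "-" & cb != "-"
  n <- sum(keep)
  if (n == 0L) return(cap_value)
  p <- sum(ca[keep] != cb[keep]) / n
  if (p >= cap_p) {
    warning("pairwise divergence ", round(p, 3), " at or above cap; distance capped")
    return(cap_value)
  }
  -log(1 - p)
}

#' Pairwise protein distance matrix
#'
#' Distances are \code{-ln(1 - p)} where p is the mismatch proportion over
#' mutually ungapped columns of the global pairwise alignment of each pair.
#' Pairs at or beyond \code{cap_p} divergence are capped at \code{cap_value}
#' with a warning.
#'
#' @param records a \code{seq_records} data.frame of proteins (>= 3 rows).
#' @param cap_p,cap_value saturation guard.
#' @return symmetric matrix with zero diagonal, labelled by record id.
#' @export
pairwise_distances <- function(records, cap_p = 0.95, cap_value = 5) {
  n <- nrow(records)
  if (is.null(n) || n < 3L) stop("need at least 3 sequences for a distance matrix")
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n)) {
      d[i, j] <- d[j, i] <- protein_distance(records$seq[i], records$seq[j],
                                             cap_p, cap_value)
    }
  d
}
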