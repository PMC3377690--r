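#' Analysis-depth gate (length and similarity test)
#'
#' Decides whether a rescued orthologous signal is strong enough for a
#' nucleotide-level forensic study.  Both the translated-hit protein and the
#' predicted protein (when one exists) are compared to the reference; the
#' study goes to the nucleotide level when \emph{either} sequence reaches
#' both the similarity and the length-ratio thresholds.  Both are tested
#' because nonsense codons shorten predictions but barely affect translated
#' hits.
#'
#' @param hit_protein concatenated translated-hit protein.
#' @param predicted predicted protein string, or NULL when no prediction.
#' @param reference reference ortholog protein.
#' @param similarity_pct,length_pct thresholds in percent.
#' @return \code{"nucleotide_level"} or \code{"protein_level"}.
#' @export
signal_gate <- function(hit_protein, predicted, reference,
                        similarity_pct = 50, length_pct = 60) {
  if (!nzchar(reference)) stop("empty reference protein")
  if (!nzchar(hit_protein)) stop("empty hit protein")
  passes <- function(s) {
    r <- global_identity(s, reference)
    r$identity_pct >= similarity_pct && r$length_ratio_pct >= length_pct
  }
  ok <- passes(hit_protein) ||
    (!is.null(predicted) && nzchar(predicted) && passes(predicted))
  if (ok) "nucleotide_level" else "protein_level"
}

#' Select the calibration pair for the divergence-consistency test
#'
#' Given the candidate species and the known orthologs, chooses the test
#' geometry: \code{distinct_lca} when two knowns have different last common
#' ancestors with the candidate (the nearer known and the most mutually
#' divergent known pair are used), \code{same_lca} when all knowns share one
#' LCA with the candidate (the two most mutually divergent knowns calibrate
#' an expected identity decay per million years).
#'
#' @param candidate_species species code of the tested sequence.
#' @param candidate_protein the tested protein string.
#' @param knowns \code{seq_records} of known ortholog proteins (one species
#'   each, species different from the candidate).
#' @param tree \code{species_tree}.
#' @return list of class \code{conservation_input} with the mode, the chosen
#'   sequences and the D1/D2/Value1/Value2 quantities.
#' @export
select_known_pair <- function(candidate_species, candidate_protein, knowns,
                              tree) {
  knowns <- knowns[knowns$species != candidate_species, , drop = FALSE]
  sp <- unique(knowns$species)
  if (length(sp) < 2L)
    stop("insufficient data: need known orthologs from at least 2 species")
  # one protein per species: keep the first
  knowns <- knowns[!duplicated(knowns$species), , drop = FALSE]
  lcas <- vapply(knowns$species, function(s)
    tree_lca(tree, c(candidate_species, s)), "")
  if (length(unique(lcas)) > 1L) {
    # distinct LCAs: nearer known vs the most divergent known pair
    dc <- vapply(knowns$species, function(s)
      divergence_time(tree, candidate_species, s), 0)
    near <- which.min(dc)
    # pick the known pair with largest mutual divergence
    best <- NULL; bestd <- -Inf
    for (i in seq_len(nrow(knowns) - 1L))
      for (j in seq(i + 1L, nrow(knowns))) {
        dij <- divergence_time(tree, knowns$species[i], knowns$species[j])
        if (dij > bestd) { bestd <- dij; best <- c(i, j) }
      }
    v1 <- global_identity(candidate_protein, knowns$seq[near])$identity_pct
    v2 <- global_identity(knowns$seq[best[1L]], knowns$seq[best[2L]])$identity_pct
    structure(list(mode = "distinct_lca",
                   near_species = knowns$species[near],
                   pair_species = knowns$species[best],
                   D1 = dc[near], D2 = bestd,
                   Value1 = v1, Value2 = v2), class = "conservation_input")
  } else {
    best <- NULL; bestd <- -Inf
    for (i in seq_len(nrow(knowns) - 1L))
      for (j in seq(i + 1L, nrow(knowns))) {
        dij <- divergence_time(tree, knowns$species[i], knowns$species[j])
        if (dij > bestd) { bestd <- dij; best <- c(i, j) }
      }
    i <- best[1L]
    v1 <- global_identity(candidate_protein, knowns$seq[i])$identity_pct
    v2 <- global_identity(knowns$seq[best[1L]], knowns$seq[best[2L]])$identity_pct
    structure(list(mode = "same_lca",
                   near_species = knowns$species[i],
                   pair_species = knowns$species[best],
                   D1 = divergence_time(tree, candidate_species,
                                        knowns$species[i]),
                   D2 = bestd,
                   Value1 = v1, Value2 = v2), class = "conservation_input")
  }
}

#' Divergence-consistency verdict on a rescued protein
#'
#' In \code{distinct_lca} geometry the verdict is \code{putative_gene} when
#' the candidate is more similar to its nearer known than the two knowns of
#' the wider pair are to each other.  In \code{same_lca} geometry a minimum
#' relative threshold \code{D2 * Value2 / D1} is computed from the
#' calibration pair, and the candidate passes when its identity
#' \code{Value1} exceeds it.  Multiplying both divergences by a common
#' factor leaves the verdict unchanged.
#'
#' @param input a \code{conservation_input} from \code{select_known_pair},
#'   or a bare list with fields \code{mode}, \code{D1}, \code{D2},
#'   \code{Value1}, \code{Value2}.
#' @return list with \code{verdict} (\code{putative_gene} or
#'   \code{putative_pseudogene}) and the audit quantities, including the
#'   threshold in \code{same_lca} mode.
#' @export
conservation_test <- function(input) {
  mode <- input$mode
  if (!mode %in% c("distinct_lca", "same_lca")) stop("unknown test mode")
  if (mode == "same_lca") {
    if (is.null(input$D1) || is.null(input$D2) || input$D1 <= 0 || input$D2 <= 0)
      stop("divergence times must be positive")
    threshold <- input$D2 * input$Value2 / input$D1
    verdict <- if (input$Value1 > threshold) "putative_gene"
               else "putative_pseudogene"
    list(verdict = verdict, mode = mode, threshold = threshold,
         D1 = input$D1, D2 = input$D2,
         Value1 = input$Value1, Value2 = input$Value2)
  } else {
    verdict <- if (input$Value1 > input$Value2) "putative_gene"
               else "putative_pseudogene"
    list(verdict = verdict, mode = mode, threshold = input$Value2,
         D1 = input$D1, D2 = input$D2,
         Value1 = input$Value1, Value2 = input$Value2)
  }
}
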