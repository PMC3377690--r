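#' Read a FASTA file of protein or DNA sequences
#'
#' Headers follow the \code{species<sep>gene_id} convention (species code
#' first).  Sequences are validated against the alphabet implied by
#' \code{kind}: the 20 amino acids plus \code{X} for proteins, \code{ACGTN}
#' for DNA.
#'
#' @param path path to a FASTA file.
#' @param kind \code{"protein"} or \code{"dna"}.
#' @param sep header token separator between species code and gene id.
#' @return a data.frame of class \code{seq_records} with columns \code{id}
#'   (full header), \code{species}, \code{gene_id}, \code{seq}, \code{kind},
#'   in file order.
#' @export
read_fasta <- function(path, kind = c("protein", "dna"), sep = "|") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: ", path, " contains no records")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  recs <- seq_records(ids, seqs, kind, sep = sep, context = path)
  recs
}

#' Build a validated collection of sequence records
#'
#' @param ids record identifiers, \code{species<sep>gene_id}.
#' @param seqs residue strings.
#' @param kind \code{"protein"} or \code{"dna"}.
#' @param sep separator inside \code{ids}.
#' @param context label used in error messages.
#' @return data.frame of class \code{seq_records}.
#' @export
seq_records <- function(ids, seqs, kind = c("protein", "dna"), sep = "|",
                        context = "input") {
  kind <- match.arg(kind)
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", context, ": ",
         ids[duplicated(ids)][1L])
  parts <- strsplit(ids, sep, fixed = TRUE)
  species <- vapply(parts, `[`, "", 1L)
  gene_id <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L], "")
  alphabet <- if (kind == "protein") setdiff(AA_ALPHABET, "*") else DNA_ALPHABET
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i]))
      stop("empty sequence for record ", ids[i], " in ", context)
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% alphabet))
    if (length(bad))
      stop("illegal ", kind, " residue '", ch[bad[1L]], "' at position ",
           bad[1L], " in record ", ids[i], " (", context, ")")
  }
  out <- data.frame(id = ids, species = species, gene_id = gene_id,
                    seq = seqs, kind = kind, stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Write sequence records to FASTA
#' @param records a \code{seq_records} data.frame.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and validate a species tree from a Newick file
#'
#' The tree must be rooted, binary, fully named (leaves and internal nodes),
#' carry branch lengths in million years, and be ultrametric within a
#' relative tolerance of the root depth.
#'
#' @param path Newick file.
#' @param tol relative ultrametricity tolerance (fraction of root depth).
#' @return a \code{species_tree} object.
#' @export
read_species_tree <- function(path, tol = 1e-6) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("Newick format error in ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick format error: could not parse ", path)
  species_tree(phy, tol = tol)
}

# ---------------------------------------------------------------------------
# Exon annotation table: tab-delimited with columns gene_id, species, chrom,
# strand, exons ("start-end,start-end", 1-based closed in the file).
# Internally exons are a 2-column matrix of 0-based half-open plus-strand
# intervals sorted by genomic start.

#' Read an exon annotation table
#' @param path tab-delimited file with columns gene_id, species, chrom,
#'   strand, exons (comma-separated \code{start-end} pairs, 1-based closed).
#' @return data.frame of class \code{exon_annotations} with a list column
#'   \code{exons} of 0-based half-open interval matrices.
#' @export
read_exon_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "chrom", "strand", "exons")
  if (!all(need %in% names(df)))
    stop("exon table must have columns ", paste(need, collapse = ", "))
  ex <- lapply(df$exons, function(s) {
    pairs <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
    m <- do.call(rbind, lapply(pairs, function(p) as.integer(p)))
    m[, 1L] <- m[, 1L] - 1L  # to 0-based half-open
    validate_exon_matrix(m)
    m
  })
  out <- df[, c("gene_id", "species", "chrom", "strand")]
  out$exons <- ex
  class(out) <- c("exon_annotations", "data.frame")
  out
}

validate_exon_matrix <- function(m) {
  if (any(m[, 2L] <= m[, 1L])) stop("empty exon interval")
  if (nrow(m) > 1L) {
    o <- order(m[, 1L])
    if (any(m[o, 1L][-1L] < m[o, 2L][-nrow(m)]))
      stop("overlapping exon intervals")
  }
  invisible(m)
}

#' Write an exon annotation table
#' @param ann an \code{exon_annotations} data.frame.
#' @param path output path.
#' @export
write_exon_table <- function(ann, path) {
  ex <- vapply(ann$exons, function(m) {
    paste(sprintf("%d-%d", m[, 1L] + 1L, m[, 2L]), collapse = ",")
  }, "")
  df <- data.frame(gene_id = ann$gene_id, species = ann$species,
                   chrom = ann$chrom, strand = ann$strand, exons = ex,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build an exon annotation set in code
#' @param gene_id,species,chrom,strand vectors, one entry per gene.
#' @param exons list of 2-column matrices (0-based half-open, plus strand).
#' @export
exon_annotations <- function(gene_id, species, chrom, strand, exons) {
  stopifnot(all(strand %in% c("+", "-")))
  lapply(exons, validate_exon_matrix)
  out <- data.frame(gene_id = gene_id, species = species, chrom = chrom,
                    strand = strand, stringsAsFactors = FALSE)
  out$exons <- exons
  class(out) <- c("exon_annotations", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Run configuration

#' Assemble a run configuration
#'
#' Thresholds (all percentages in [0, 100] unless noted):
#' \describe{
#'   \item{test1_length_pct}{minimum candidate/reference length ratio for a
#'     nucleotide-level study (default 60).}
#'   \item{test1_similarity_pct}{minimum percent identity for a
#'     nucleotide-level study (default 50).}
#'   \item{test3_max_divergence_pct}{known orthologs more divergent than this
#'     are dropped from the reconstruction set (default 60).}
#'   \item{chain_max_gap_nt}{maximum genomic gap when chaining translated
#'     hits (default 50000 nt).}
#'   \item{locus_flank_nt}{flank added around a chained locus (default 5000).}
#'   \item{compaction_flank_nt}{intron context kept at each exon junction
#'     after alignment compaction (default 20 nt).}
#' }
#'
#' @param ancestor internal node of the species tree under which losses are
#'   studied.
#' @param mode \code{"simple"} (presence/absence only) or \code{"complete"}
#'   (genome-level rescue and forensics).
#' @param thresholds named numeric overrides of the defaults above.
#' @param excluded_gene_ids annotation ids ignored during the annotated-gene
#'   check (re-annotation relaunches).
#' @param scan_subfamilies also enumerate sub-family roots (speciation nodes
#'   established after a duplication) along the query lineage and report the
#'   species missing from each sub-family.
#' @param seed integer seed for all stochastic steps.
#' @export
run_config <- function(ancestor, mode = c("complete", "simple"),
                       thresholds = list(), excluded_gene_ids = character(),
                       scan_subfamilies = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  th <- list(test1_length_pct = 60, test1_similarity_pct = 50,
             test3_max_divergence_pct = 60, chain_max_gap_nt = 50000,
             locus_flank_nt = 5000, compaction_flank_nt = 20,
             search_score_min = 50, search_kmer = 4,
             predict_score_frac = 0.4, candidate_cap = 5,
             homolog_min_identity_pct = 30, homolog_top_n = 3)
  for (nm in names(thresholds)) {
    if (!nm %in% names(th)) stop("unknown threshold: ", nm)
    th[[nm]] <- thresholds[[nm]]
  }
  pct <- c("test1_length_pct", "test1_similarity_pct",
           "test3_max_divergence_pct", "homolog_min_identity_pct")
  for (nm in pct)
    if (th[[nm]] < 0 || th[[nm]] > 100)
      stop(nm, " must be in [0, 100]")
  structure(list(ancestor = ancestor, mode = mode, thresholds = th,
                 excluded_gene_ids = excluded_gene_ids,
                 scan_subfamilies = isTRUE(scan_subfamilies),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with fields ancestor, mode, thresholds, excluded_gene_ids, seed.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(ancestor = y$ancestor,
             mode = if (is.null(y$mode)) "complete" else y$mode,
             thresholds = if (is.null(y$thresholds)) list() else y$thresholds,
             excluded_gene_ids = if (is.null(y$excluded_gene_ids)) character()
                                 else as.character(y$excluded_gene_ids),
             scan_subfamilies = isTRUE(y$scan_subfamilies),
             seed = if (is.null(y$seed)) 1L else y$seed)
}
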