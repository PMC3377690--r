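# helper: build a 2-exon locus set (reference + relatives) with a planted
# edit in the descendant; returns sequences plus the reference exon matrix
two_exon_family <- function(seed = 1, exon1 = 60L, exon2 = 60L,
                            intron = 90L, flankdna = 120L) {
  set.seed(seed)
  prot <- ref_prot(seed, (exon1 + exon2) / 3)
  cds <- lineageloss:::back_translate(prot)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  intr <- paste0("GT", bg(intron - 4L), "AG")
  gene <- paste0(substr(cds, 1, exon1), intr,
                 substr(cds, exon1 + 1, exon1 + exon2))
  left <- bg(flankdna); right <- bg(flankdna)
  locus <- paste0(left, gene, right)
  exons <- cbind(c(flankdna, flankdna + exon1 + intron),
                 c(flankdna + exon1, flankdna + exon1 + intron + exon2))
  list(locus = locus, exons = exons, exon1 = exon1, exon2 = exon2,
       flank = flankdna, intron = intron)
}

test_that("one sequence per species is kept and divergent knowns dropped", {
  cand <- data.frame(species = "Hsa", id = "Hsa|c", seq = "ACGT",
                     identity_pct = 80, stringsAsFactors = FALSE)
  kn <- data.frame(species = c("Mus", "Mus", "Rno", "Mdo"),
                   id = c("Mus|1", "Mus|2", "Rno|1", "Mdo|1"),
                   seq = c("AAAA", "CCCC", "TTTT", "GGGG"),
                   identity_pct = c(70, 90, 60, 20), stringsAsFactors = FALSE)
  out <- select_reconstruction_set(cand, kn, max_divergence_pct = 50)
  expect_setequal(out$species, c("Hsa", "Mus", "Rno"))
  expect_equal(out$id[out$species == "Mus"], "Mus|2")
  expect_true(all(out$is_candidate == (out$species == "Hsa")))
  expect_error(select_reconstruction_set(cand, kn[4, ], 50), "insufficient")
})

test_that("identity alignment retains exons plus junction flanks", {
  fam <- two_exon_family(1)
  seqs <- c(A = fam$locus, B = fam$locus, C = fam$locus)
  aln <- build_guided_alignment(seqs, "A", fam$exons, flank = 20L)
  expect_equal(ncol(aln$matrix), fam$exon1 + fam$exon2 + 2L * 2L * 20L)
  expect_true(all(aln$matrix != "-"))
  # projection on a gap-free row equals the exon coordinates shifted
  e1 <- aln$exon_cols[[1L]]
  expect_equal(e1[2L] - e1[1L] + 1L, fam$exon1)
  expect_equal(unname(aln$column_map["A", e1[1L]]), fam$exons[1L, 1L])
})

test_that("a large mid-intron insert disappears after compaction", {
  fam <- two_exon_family(2)
  ins_at <- fam$flank + fam$exon1 + 45L
  with_ins <- paste0(substr(fam$locus, 1, ins_at),
                     strrep("ACGT", 75),
                     substr(fam$locus, ins_at + 1, nchar(fam$locus)))
  seqs <- c(A = fam$locus, B = with_ins, C = fam$locus)
  aln <- build_guided_alignment(seqs, "A", fam$exons, flank = 20L)
  expect_equal(ncol(aln$matrix), fam$exon1 + fam$exon2 + 80L)
})

test_that("ancestral reconstruction is exact on trivial inputs", {
  fam <- two_exon_family(3)
  seqs <- c(Hsa = fam$locus, Ptr = fam$locus, Mus = fam$locus)
  aln <- build_guided_alignment(seqs, "Hsa", fam$exons, flank = 20L)
  rec <- reconstruct_ancestors(aln, tree3()$phylo)
  expect_equal(unname(rec$rows["Eth"]), unname(aln$rows[["Hsa"]]))
  expect_equal(rec$cost, 0)
  # one row differing at one column: ancestors carry the majority state
  v <- strsplit(fam$locus, "")[[1L]]
  pos <- fam$flank + 30L
  v[pos] <- setdiff(c("A", "C", "G", "T"), v[pos])[1L]
  seqs2 <- c(Hsa = paste(v, collapse = ""), Ptr = fam$locus, Mus = fam$locus)
  aln2 <- build_guided_alignment(seqs2, "Ptr", fam$exons, flank = 20L)
  rec2 <- reconstruct_ancestors(aln2, tree3()$phylo)
  expect_equal(rec2$cost, 1)
  expect_equal(unname(rec2$rows["Eth"]), unname(aln2$rows[["Mus"]]))
})

test_that("parsimony cost equals the exhaustive minimum on small alignments", {
  tr <- tree4()
  for (seed in 1:10) {
    set.seed(seed)
    L <- 12L
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), 4L * L, TRUE,
                         prob = c(0.22, 0.22, 0.22, 0.22, 0.12)),
                  4L, L, dimnames = list(c("Hsa", "Ptr", "Mmu", "Mus"), NULL))
    aln <- structure(list(matrix = mat,
                          rows = apply(mat, 1, paste, collapse = ""),
                          exon_cols = list(c(1L, L)),
                          reference_species = "Hsa", flank = 0L),
                     class = "compacted_alignment")
    rec <- reconstruct_ancestors(aln, tr$phylo)
    expect_equal(rec$cost, brute_parsimony_cost(tr$phylo, mat))
  }
})

test_that("planted mutations are recovered exactly against a true ancestor", {
  fam <- two_exon_family(5)
  anc <- fam$locus
  v <- strsplit(anc, "")[[1L]]
  # nonsense at codon 5 of exon 2
  cod_start <- fam$exons[2L, 1L] + 3L * 4L
  v[(cod_start + 1L):(cod_start + 3L)] <- c("T", "A", "A")
  desc_nonsense <- paste(v, collapse = "")
  seqs <- c(R = anc, A = anc, D = desc_nonsense)
  aln <- build_guided_alignment(seqs, "R", fam$exons, flank = 20L)
  muts <- scan_pair(aln$rows[["D"]], aln$rows[["A"]], aln)
  expect_equal(nrow(muts), 1L)
  expect_equal(muts$kind, "nonsense")
  expect_equal(muts$exon, 2L)
  expect_equal(muts$position, 5L)

  # identical rows: silence
  expect_equal(nrow(scan_pair(aln$rows[["A"]], aln$rows[["A"]], aln)), 0L)
})

test_that("a 2 nt deletion plus donor edit yields deletion+frameshift+splice", {
  fam <- two_exon_family(6)
  v <- strsplit(fam$locus, "")[[1L]]
  # donor GT -> GC at junction 1
  v[fam$exons[1L, 2L] + 2L] <- "C"
  # 2 nt deletion inside exon 1 (remove nt 31-32)
  del_at <- fam$exons[1L, 1L] + 30L
  v <- v[-c(del_at + 1L, del_at + 2L)]
  desc <- paste(v, collapse = "")
  seqs <- c(R = fam$locus, A = fam$locus, D = desc)
  aln <- build_guided_alignment(seqs, "R", fam$exons, flank = 20L)
  muts <- scan_pair(aln$rows[["D"]], aln$rows[["A"]], aln)
  expect_setequal(muts$kind, c("deletion", "frameshift", "splice_donor"))
  del <- muts[muts$kind == "deletion", ]
  expect_equal(del$exon, 1L)
  expect_equal(del$length, 2L)
  expect_equal(muts$detail[muts$kind == "splice_donor"], "GC")
})

test_that("start and stop losses are detected at the projected termini", {
  # build a gene whose exon 1 starts with ATG and exon 2 ends with TAA
  set.seed(8)
  prot <- paste0("M", ref_prot(8, 39))
  cds <- paste0(lineageloss:::back_translate(prot), "TAA")
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  intr <- paste0("GT", bg(56), "AG")
  locus <- paste0(bg(100), substr(cds, 1, 60), intr,
                  substr(cds, 61, nchar(cds)), bg(100))
  exons <- cbind(c(100L, 160L + 60L), c(160L, 160L + 60L + 63L))
  v <- strsplit(locus, "")[[1L]]
  v[101:103] <- c("A", "T", "A")                 # start ATG -> ATA
  v[(160L + 60L + 61L):(160L + 60L + 63L)] <- c("C", "A", "A")  # stop -> CAA
  desc <- paste(v, collapse = "")
  seqs <- c(R = locus, A = locus, D = desc)
  aln <- build_guided_alignment(seqs, "R", exons, flank = 15L)
  muts <- scan_pair(aln$rows[["D"]], aln$rows[["A"]], aln)
  expect_setequal(muts$kind, c("start_loss", "stop_loss"))
})

test_that("exon loss is reported once and masks point scans of that exon", {
  fam <- two_exon_family(9)
  v <- strsplit(fam$locus, "")[[1L]]
  v <- v[-seq(fam$exons[2L, 1L] + 1L, fam$exons[2L, 2L])]
  desc <- paste(v, collapse = "")
  seqs <- c(R = fam$locus, A = fam$locus, D = desc)
  aln <- build_guided_alignment(seqs, "R", fam$exons, flank = 20L)
  muts <- scan_pair(aln$rows[["D"]], aln$rows[["A"]], aln)
  expect_true("exon_loss" %in% muts$kind)
  expect_equal(muts$exon[muts$kind == "exon_loss"], 2L)
  expect_false(any(muts$kind %in% c("nonsense", "deletion")))
})

test_that("lineage scans attribute shared mutations to the stem branch", {
  p <- sim_params(seed = 21, subst_rate = 0, planted_events = list(
    list(branch = "Hpa", kind = "pseudogenization",
         recipe = list(nonsense = 1))))
  sim <- simulate_family(p)
  sc <- scan_family(sim)
  for (target in c("Hsa", "Ptr")) {
    rep <- sc$reports[[target]]
    expect_equal(nrow(rep), 1L)
    expect_equal(rep$branch, "Hpa")
    expect_equal(rep$kind, "nonsense")
  }
  # independent terminal mutations stay on their own branches
  p2 <- sim_params(seed = 22, subst_rate = 0, planted_events = list(
    list(branch = "Hsa", kind = "pseudogenization",
         recipe = list(nonsense = 1)),
    list(branch = "Mus", kind = "pseudogenization",
         recipe = list(splice_donor = 1))))
  sc2 <- scan_family(simulate_family(p2))
  expect_equal(sc2$reports$Hsa$branch, "Hsa")
  expect_equal(sc2$reports$Mus$branch, "Mus")
  # clean family: all reports empty
  sc3 <- scan_family(simulate_family(sim_params(seed = 23, subst_rate = 0)))
  expect_length(sc3$reports, 0L)
})

test_that("classification condemns on disabling kinds only and is monotone", {
  expect_equal(classify_sequence(lineageloss:::empty_mutations()), "intact")
  non <- data.frame(kind = "nonsense", exon = 1L, position = 2L, detail = "",
                    length = NA_integer_, stringsAsFactors = FALSE)
  expect_equal(classify_sequence(non), "pseudogene")
  inframe <- data.frame(kind = "deletion", exon = 1L, position = 2L,
                        detail = "", length = 3L, stringsAsFactors = FALSE)
  expect_equal(classify_sequence(inframe), "intact")
  # monotone: adding any mutation never flips pseudogene -> intact
  expect_equal(classify_sequence(rbind(non, inframe)), "pseudogene")
})
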