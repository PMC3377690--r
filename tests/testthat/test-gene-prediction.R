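plant_locus <- function(prot, introns = integer(0), seed = 1, flank = 300,
                        break_points = NULL) {
  # build a locus containing the back-translated CDS, optionally split by
  # GT..AG introns after the given codon indices
  set.seed(seed)
  cds <- lineageloss:::back_translate(prot)
  if (length(introns)) {
    if (is.null(break_points))
      break_points <- sort(sample(seq(10, nchar(prot) - 10), length(introns)))
    pieces <- substring(cds, c(1, break_points * 3 + 1),
                        c(break_points * 3, nchar(cds)))
    ins <- vapply(introns, function(L) paste0(
      "GT", paste(sample(c("A", "C", "T"), L - 4, TRUE), collapse = ""), "AG"),
      "")
    body <- paste0(paste0(pieces[-length(pieces)], ins, collapse = ""),
                   pieces[length(pieces)])
  } else body <- cds
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  list(seq = paste0(bg(flank), body, bg(flank)), start = flank,
       break_points = break_points)
}

test_that("a planted single-exon gene is predicted exactly", {
  prot <- ref_prot(5, 80)
  loc <- plant_locus(prot, seed = 5)
  pred <- predict_protein(loc$seq, prot)
  expect_equal(pred$protein, prot)
  expect_equal(nrow(pred$exons), 1L)
  expect_equal(pred$exons[1L, 1L], loc$start)
})

test_that("an intron-split gene is predicted with the junction at the plant", {
  prot <- ref_prot(6, 80)
  loc <- plant_locus(prot, introns = 100L, seed = 6, break_points = 40L)
  pred <- predict_protein(loc$seq, prot)
  expect_equal(pred$protein, prot)
  expect_equal(nrow(pred$exons), 2L)
  expect_equal(pred$exons[1L, 2L] - pred$exons[1L, 1L], 120L)
  expect_equal(pred$splice_sites$donor, "GT")
  expect_equal(pred$splice_sites$acceptor, "AG")
})

test_that("an in-frame nonsense codon is excluded from the prediction", {
  prot <- ref_prot(7, 50)
  cds <- lineageloss:::back_translate(prot)
  substr(cds, 28, 30) <- "TAA"   # codon 10 of 50
  set.seed(7)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  locus <- paste0(bg(200), cds, bg(200))
  pred <- predict_protein(locus, prot)
  expect_false(is.null(pred))
  expect_lt(nchar(pred$protein), nchar(prot))
  expect_false(grepl("*", pred$protein, fixed = TRUE))
})

test_that("predictions translate their exons exactly and without stops", {
  for (seed in 1:8) {
    prot <- ref_prot(seed, 60 + 5 * seed)
    ni <- seed %% 3
    loc <- plant_locus(prot, introns = rep(60L, ni), seed = seed)
    pred <- predict_protein(loc$seq, prot)
    expect_false(is.null(pred))
    cds <- paste(substring(loc$seq, pred$exons[, 1L] + 1L, pred$exons[, 2L]),
                 collapse = "")
    expect_equal(lineageloss:::translate_dna(cds), pred$protein)
    expect_false(grepl("*", pred$protein, fixed = TRUE))
    expect_gte(global_identity(pred$protein, prot)$identity_pct, 95)
  }
})

test_that("extra flanking DNA does not change an interior prediction", {
  prot <- ref_prot(9, 70)
  loc <- plant_locus(prot, introns = 80L, seed = 9, break_points = 35L)
  pred1 <- predict_protein(loc$seq, prot)
  set.seed(99)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  pred2 <- predict_protein(paste0(bg(500), loc$seq, bg(500)), prot)
  expect_equal(pred2$protein, pred1$protein)
  expect_equal(nrow(pred2$exons), nrow(pred1$exons))
})

test_that("a junk locus yields no prediction", {
  set.seed(3)
  junk <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  expect_null(predict_protein(junk, ref_prot(3, 100)))
})

test_that("annotated-gene lookup respects overlap, exclusion and emptiness", {
  ann <- exon_annotations(gene_id = c("gA", "gB"), species = c("Hsa", "Hsa"),
                          chrom = c("chr1", "chr1"), strand = c("+", "+"),
                          exons = list(cbind(1000L, 2000L),
                                       cbind(2500L, 2600L)))
  expect_equal(find_annotated_gene_at_locus(ann, "Hsa", "chr1",
                                            c(1500L, 3000L)), "gA")
  expect_null(find_annotated_gene_at_locus(ann, "Hsa", "chr1",
                                           c(1500L, 3000L),
                                           excluded = c("gA", "gB")))
  expect_null(find_annotated_gene_at_locus(ann, "Hsa", "chr9",
                                           c(1500L, 3000L)))
  expect_null(find_annotated_gene_at_locus(ann, "Mus", "chr1",
                                           c(1500L, 3000L)))
  expect_null(find_annotated_gene_at_locus(NULL, "Hsa", "chr1", c(0L, 10L)))
})
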