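test_that("six-frame translation uses the standard code with * and X", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr[["+0"]], "MK")
  expect_equal(six_frame_translate("TAA")[["+0"]], "*")
  # reverse complement of TTACAT is ATGTAA
  expect_equal(six_frame_translate("TTACAT")[["-0"]], "M*")
  expect_equal(six_frame_translate("ATGNAA")[["+0"]], "MX")
})

make_genome <- function(prot, pos = 4000, total = 10000, seed = 1,
                        strand = "+") {
  set.seed(seed)
  bt <- lineageloss:::back_translate(prot)
  bg <- paste(sample(c("A", "C", "G", "T"), total, TRUE), collapse = "")
  chrom <- paste0(substr(bg, 1, pos), bt,
                  substr(bg, pos + 1, total - nchar(bt)))
  if (strand == "-")
    chrom <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chrom)))
  list(chr1 = chrom)
}

test_that("a planted exact back-translation dominates the hit list", {
  prot <- ref_prot()
  g <- make_genome(prot, pos = 4000, seed = 2)
  hits <- translated_search(prot, g)
  expect_gt(nrow(hits), 0L)
  top <- hits[1L, ]
  expect_equal(top$strand, "+")
  expect_lte(abs(top$genome_start - 4000), 3)
  expect_equal(top$genome_end - top$genome_start, 3L * nchar(prot))
})

test_that("minus-strand plants are reported with plus-strand coordinates", {
  prot <- ref_prot(7)
  g <- make_genome(prot, pos = 4000, total = 10000, seed = 3, strand = "-")
  hits <- translated_search(prot, g)
  expect_gt(nrow(hits), 0L)
  top <- hits[1L, ]
  expect_equal(top$strand, "-")
  n <- nchar(g$chr1)
  # plant occupied [4000, 4000 + 3L) on the original strand, so it sits at
  # [n - end, n - start) after reverse complementing
  expect_lte(abs((n - top$genome_end) - 4000), 3)
  # extracting and translating the located span recovers the protein signal
  seg <- substr(g$chr1, top$genome_start + 1, top$genome_end)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  expect_equal(lineageloss:::translate_dna(rc), prot)
})

test_that("random genomes with no plant yield no hits above threshold", {
  prot <- ref_prot(11)
  misses <- 0L
  for (seed in 1:10) {
    set.seed(seed + 100)
    g <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 50000, TRUE),
                           collapse = ""))
    misses <- misses + (nrow(translated_search(prot, g)) == 0L)
  }
  expect_gte(misses, 9L)
})

test_that("chaining respects gap, strand and collinearity rules", {
  h <- data.frame(chrom = "chr1", strand = "+", frame = 0L,
                  genome_start = c(1000L, 6000L), genome_end = c(1300L, 6300L),
                  protein_start = c(1L, 101L), protein_end = c(100L, 200L),
                  score = c(120, 130), hit_protein = c("A", "B"),
                  stringsAsFactors = FALSE)
  class(h) <- c("translated_hits", "data.frame")
  one <- chain_hits(h, max_gap = 10000)
  expect_length(one, 1L)
  expect_equal(one[[1L]]$total_score, 250)
  expect_equal(one[[1L]]$hits$genome_start, c(1000L, 6000L))
  two <- chain_hits(h, max_gap = 1000)
  expect_length(two, 2L)
  h2 <- h; h2$strand <- c("+", "-")
  expect_length(chain_hits(h2, max_gap = 10000), 2L)
  # anti-collinear protein order never chains
  h3 <- h; h3$protein_start <- c(101L, 1L); h3$protein_end <- c(200L, 100L)
  expect_length(chain_hits(h3, max_gap = 10000), 2L)
})

test_that("locus extraction clamps at chromosome ends and handles strand", {
  g <- list(chr1 = paste(rep("ACGT", 2500), collapse = ""))
  cand <- structure(list(chrom = "chr1", strand = "+",
                         span = c(4000L, 4900L), total_score = 1,
                         hits = NULL, concatenated_protein = ""),
                    class = "locus_candidate")
  loc <- extract_locus(g, cand, flank = 2000)
  expect_equal(loc$offset, 2000L)
  expect_equal(nchar(loc$seq), 4900 - 4000 + 4000)
  cand$span <- c(100L, 500L)
  loc2 <- extract_locus(g, cand, flank = 2000)
  expect_equal(loc2$offset, 0L)
  cand$strand <- "-"
  loc3 <- extract_locus(g, cand, flank = 2000)
  plus <- substr(g$chr1, 1, 2500)
  expect_equal(loc3$seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus))))
  # local-to-genome mapping stays inside the chromosome
  m <- locus_to_genome(loc3, 0L, 10L)
  expect_true(all(m >= 0 & m <= nchar(g$chr1)))
})

test_that("diverged planted homologs are still ranked first", {
  found <- 0L
  for (seed in 1:10) {
    prot <- ref_prot(seed, 100)
    set.seed(seed)
    # ~40% amino-acid substitutions: a distant but findable homolog
    v <- strsplit(prot, "")[[1L]]
    idx <- sample(length(v), 40)
    v[idx] <- sample(names(lineageloss:::PREFERRED_CODON), 40, TRUE)
    g <- make_genome(paste(v, collapse = ""), pos = 3000, seed = seed + 20)
    hits <- translated_search(prot, g)
    if (nrow(hits) && abs(hits$genome_start[1L] - 3000) < 50) found <- found + 1L
  }
  expect_gte(found, 9L)
})
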