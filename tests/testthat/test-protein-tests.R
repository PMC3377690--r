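test_that("global identity on simple pairs", {
  r <- global_identity("ACDE", "ACDE")
  expect_equal(r$identity_pct, 100)
  expect_equal(r$length_ratio_pct, 100)
  r2 <- global_identity("ACDE", "ACDF")
  expect_equal(r2$identity_pct, 75)
  expect_error(global_identity("", "ACDE"), "empty")
})

test_that("alignment scores match the exhaustive brute-force oracle", {
  set.seed(1)
  alpha <- c("A", "C", "D", "E")
  pool <- replicate(10, paste(sample(alpha, sample(1:6, 1), TRUE),
                              collapse = ""))
  pairs <- t(combn(length(pool), 2))
  for (k in seq_len(nrow(pairs))) {
    a <- pool[pairs[k, 1]]; b <- pool[pairs[k, 2]]
    expect_equal(nw_align(a, b)$score, brute_global_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scores match an independent implementation on longer pairs", {
  set.seed(2)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aas <- setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "")
  for (k in 1:200) {
    a <- paste(sample(aas, sample(4:12, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(4:12, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = BLOSUM62,
                                         gapOpening = 10, gapExtension = 0.5,
                                         type = "global", scoreOnly = TRUE)
    expect_equal(nw_align(a, b)$score, ref, info = paste(a, b))
  }
})

test_that("the analysis-depth gate routes by either tested sequence", {
  ref <- ref_prot(1, 100)
  good <- ref                       # 100 % identity, 100 % length
  poor <- substr(ref, 1, 30)        # short fragment
  expect_equal(signal_gate(good, NULL, ref), "nucleotide_level")
  expect_equal(signal_gate(poor, NULL, ref), "protein_level")
  # a failing hit is rescued by a passing prediction, and vice versa
  expect_equal(signal_gate(poor, good, ref), "nucleotide_level")
  expect_equal(signal_gate(good, poor, ref), "nucleotide_level")
  # thresholds are respected
  expect_equal(signal_gate(good, NULL, ref, similarity_pct = 101),
               "protein_level")
})

test_that("the same-LCA conservation threshold follows D2*Value2/D1", {
  r <- conservation_test(list(mode = "same_lca", D1 = 90, D2 = 30,
                              Value1 = 45, Value2 = 90))
  expect_equal(r$threshold, 30)
  expect_equal(r$verdict, "putative_gene")
  r2 <- conservation_test(list(mode = "same_lca", D1 = 90, D2 = 30,
                               Value1 = 20, Value2 = 90))
  expect_equal(r2$verdict, "putative_pseudogene")
  expect_error(conservation_test(list(mode = "same_lca", D1 = 0, D2 = 30,
                                      Value1 = 10, Value2 = 90)), "positive")
})

test_that("the same-LCA verdict is scale invariant in the divergences", {
  for (c_ in c(0.1, 1, 7, 250)) {
    r <- conservation_test(list(mode = "same_lca", D1 = 90 * c_, D2 = 30 * c_,
                                Value1 = 45, Value2 = 90))
    expect_equal(r$verdict, "putative_gene")
  }
})

test_that("raising Value1 can only rescue, never condemn", {
  prev <- "putative_pseudogene"
  for (v1 in seq(0, 100, by = 5)) {
    r <- conservation_test(list(mode = "same_lca", D1 = 60, D2 = 30,
                                Value1 = v1, Value2 = 80))
    if (prev == "putative_gene") expect_equal(r$verdict, "putative_gene")
    prev <- r$verdict
  }
  expect_equal(prev, "putative_gene")
})

test_that("the distinct-LCA rule compares the two identities directly", {
  r <- conservation_test(list(mode = "distinct_lca", D1 = 90, D2 = 160,
                              Value1 = 70, Value2 = 55))
  expect_equal(r$verdict, "putative_gene")
  r2 <- conservation_test(list(mode = "distinct_lca", D1 = 90, D2 = 160,
                               Value1 = 50, Value2 = 55))
  expect_equal(r2$verdict, "putative_pseudogene")
})

test_that("known-pair selection distinguishes the two test geometries", {
  tr <- tree8()
  knowns <- seq_records(c("Mus|g", "Mdo|g"),
                        c(ref_prot(1, 60), ref_prot(2, 60)), "protein")
  # candidate Hsa: LCA with Mus is Eth, with Mdo is The -> distinct
  inp <- select_known_pair("Hsa", ref_prot(3, 60), knowns, tr)
  expect_equal(inp$mode, "distinct_lca")
  expect_equal(inp$near_species, "Mus")
  expect_equal(inp$D2, 160)
  # candidate Mus vs {Hsa, Mmu}: both LCAs at Eth -> same geometry
  knowns2 <- seq_records(c("Hsa|g", "Mmu|g"),
                         c(ref_prot(4, 60), ref_prot(5, 60)), "protein")
  inp2 <- select_known_pair("Mus", ref_prot(6, 60), knowns2, tr)
  expect_equal(inp2$mode, "same_lca")
  expect_setequal(inp2$pair_species, c("Hsa", "Mmu"))
  expect_equal(inp2$D1, 90)
  expect_equal(inp2$D2, 30)
  expect_error(select_known_pair("Hsa", "MKV", knowns[1, ], tr),
               "insufficient")
})
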