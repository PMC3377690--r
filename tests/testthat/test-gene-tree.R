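test_that("pairwise distances follow -ln(1 - p) on ungapped columns", {
  recs <- seq_records(c("A|a", "B|b", "C|c"),
                      c("MKVLMAWPTE", "MKVLMAWPTD", "MKVLMAWPTE"), "protein")
  d <- pairwise_distances(recs)
  expect_equal(d["A|a", "B|b"], -log(0.9))
  expect_equal(d["A|a", "C|c"], 0)
  expect_equal(d, t(d))
  expect_equal(diag(d), c("A|a" = 0, "B|b" = 0, "C|c" = 0))
  expect_error(pairwise_distances(recs[1:2, ]), "at least 3")
})

test_that("identical sequences give a zero distance matrix", {
  recs <- seq_records(paste0(c("A", "B", "C"), "|g"),
                      rep("MKVLMAWPTE", 3), "protein")
  d <- pairwise_distances(recs)
  expect_true(all(d == 0))
})

test_that("neighbor joining recovers additive topologies", {
  # fixed 4-taxon additive case
  phy <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  dm <- ape::cophenetic.phylo(phy)
  nj <- build_nj(dm)
  expect_true(same_topology(nj, phy))
  # 3 taxa: the unique topology
  nj3 <- build_nj(ape::cophenetic.phylo(ape::read.tree(text = "(A:1,B:2,C:3);")))
  expect_equal(length(nj3$tip.label), 3L)
  # seeded random additive matrices, cross-checked against ape::nj
  for (seed in 1:25) {
    ra <- random_additive(4 + seed %% 9, seed)
    mine <- build_nj(ra$d)
    expect_true(same_topology(mine, ra$tree))
    expect_true(same_topology(mine, ape::nj(ra$d)))
  }
  expect_error(build_nj(matrix(NaN, 3, 3,
                               dimnames = list(letters[1:3], letters[1:3]))),
               "NA/NaN")
})

test_that("reconciliation labels congruent one-copy families as speciations", {
  tr <- tree3()
  phy <- ape::read.tree(text = "((Hsa|g:1,Ptr|g:1):1,Mus|g:2);")
  rec <- reconcile(phy, tr)
  expect_equal(rec$n_dup, 0L)
  expect_setequal(rec$label[rec$label != "leaf"], "speciation")
})

test_that("a within-species duplication maps to the species and is labelled", {
  tr <- tree3()
  phy <- ape::read.tree(text = "((Hsa|1:1,Hsa|2:1):1,Mus|1:2);")
  rec <- reconcile(phy, tr)
  n_tip <- 3L
  inner <- which(rec$label == "duplication")
  expect_length(inner, 1L)
  expect_equal(rec$mapping[inner], "Hsa")
  expect_error(reconcile(ape::read.tree(text = "((Xx|1:1,Hsa|1:1):1,Mus|1:2);"),
                         tr), "not in species tree")
})

test_that("reconciliation agrees with an independent LCA recomputation", {
  tr <- tree8()
  pool <- c("Hsa", "Ptr", "Mmu", "Mus", "Rno", "Mdo")
  for (seed in 1:60) {
    phy <- random_gene_tree(pool, 4 + seed %% 7, seed)
    rec <- reconcile(phy, tr)
    oracle <- brute_reconcile(phy, tr)
    expect_equal(rec$mapping, oracle$mapping)
    expect_equal(rec$label, oracle$label)
  }
})

test_that("rooting minimises duplications and is leaf-order invariant", {
  tr <- tree3()
  # congruent single-copy family: optimal rooting has zero duplications
  phy <- ape::unroot(ape::read.tree(text = "((Hsa|g:1,Ptr|g:1):1,Mus|g:2);"))
  rooted <- root_gene_tree(phy, tr)
  expect_equal(reconcile(rooted, tr)$n_dup, 0L)
  # ((Hsa_1,Hsa_2),Mus_1): the minimum is one duplication
  phy2 <- ape::unroot(ape::read.tree(text = "((Hsa|1:1,Hsa|2:1):1,Mus|1:2);"))
  rooted2 <- root_gene_tree(phy2, tr)
  expect_equal(reconcile(rooted2, tr)$n_dup, 1L)
  # invariance to leaf order
  phy3 <- ape::read.tree(text = "(Mus|1:2,(Hsa|2:1,Hsa|1:1):1);")
  rooted3 <- root_gene_tree(ape::unroot(phy3), tr)
  expect_true(same_topology(rooted2, rooted3))
  expect_equal(sort(leaves_under_root_child(rooted2)),
               sort(leaves_under_root_child(rooted3)))
})

fig1_gene_tree <- function() {
  # two catarrhine sub-families born by duplication, plus the Mus ortholog;
  # the human copy is missing from the sub-family containing the query
  ape::read.tree(text = paste0(
    "(((Ptr|g1:1,Mmu|g1:1):1,((Hsa|g2:0.5,Ptr|g2:0.5):0.5,Mmu|g2:1):1):1,",
    "Mus|g1:2);"))
}

test_that("ortholog group extraction follows the worked two-sub-family case", {
  tr <- tree4()
  rec <- reconcile(fig1_gene_tree(), tr)
  # at the eutherian ancestor every gene is co-orthologous to the query
  grp_eth <- extract_ortholog_group(rec, "Mmu|g1", "Eth", tr)
  expect_setequal(grp_eth$members,
                  c("Ptr|g1", "Mmu|g1", "Hsa|g2", "Ptr|g2", "Mmu|g2", "Mus|g1"))
  expect_equal(missing_species(grp_eth, tr, "Eth"), character(0))
  # at the catarrhine ancestor only the query's sub-family counts
  grp_ctr <- extract_ortholog_group(rec, "Mmu|g1", "Ctr", tr)
  expect_setequal(grp_ctr$members, c("Ptr|g1", "Mmu|g1"))
  expect_equal(missing_species(grp_ctr, tr, "Ctr"), "Hsa")
})

test_that("full-tree group and empty complements behave", {
  tr <- tree3()
  rec <- reconcile(ape::read.tree(text = "((Hsa|g:1,Ptr|g:1):1,Mus|g:2);"), tr)
  grp <- extract_ortholog_group(rec, "Hsa|g", "Eth", tr)
  expect_setequal(grp$members, c("Hsa|g", "Ptr|g", "Mus|g"))
  expect_equal(missing_species(grp, tr, "Eth"), character(0))
  expect_setequal(missing_species(NULL, tr, "Eth"), c("Hsa", "Ptr", "Mus"))
})

test_that("sub-family roots are speciation nodes under a duplication", {
  tr <- tree3()
  # no duplications: empty
  rec0 <- reconcile(ape::read.tree(text = "((Hsa|g:1,Ptr|g:1):1,Mus|g:2);"), tr)
  expect_length(enumerate_subfamily_roots(rec0, "Hsa|g", "Eth", tr), 0L)
  # ((Hsa_1,Mus_1),(Hsa_2,Mus_2)) duplicated at the root ancestor
  phy <- ape::read.tree(
    text = "((Hsa|1:2,Mus|1:2):1,(Hsa|2:2,Mus|2:2):1);")
  rec <- reconcile(phy, tr)
  roots <- enumerate_subfamily_roots(rec, "Hsa|1", "Eth", tr)
  expect_length(roots, 1L)
  expect_setequal(lineageloss:::leaves_under_phylo(phy, roots),
                  c("Hsa|1", "Mus|1"))
})

test_that("reconciled trees serialise with NHX duplication tags", {
  tr <- tree3()
  rec <- reconcile(ape::read.tree(text = "((Hsa|1:1,Hsa|2:1):1,Mus|1:2);"), tr)
  f <- withr::local_tempfile(fileext = ".nhx")
  write_reconciled_tree(rec, f)
  txt <- readLines(f)
  expect_match(txt, "D=Y", fixed = TRUE)
  expect_match(txt, "D=N", fixed = TRUE)
})
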