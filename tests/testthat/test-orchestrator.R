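run_sim_study <- function(p, mode = "complete", ancestor = "Eth",
                          seed = p$seed, query_species = "Mus", ...) {
  sim <- simulate_family(p)
  cfg <- run_config(ancestor = ancestor, mode = mode, seed = seed, ...)
  q <- sim$proteome$id[sim$proteome$species == query_species][1L]
  list(sim = sim,
       report = run_study(q, sim$proteome, sim$tree, cfg,
                          genomes = sim$genomes,
                          annotations = sim$annotations))
}

test_that("a planted terminal loss is reported as Lost with a branch event", {
  r <- run_sim_study(sim_params(seed = 41, planted_events = list(
    list(branch = "Hsa", kind = "loss"))))
  expect_equal(unname(r$report$verdicts[["Hsa"]]), "Lost")
  ev <- r$report$events$events
  expect_equal(ev$event[ev$branch == "Hsa"], "gene_loss")
})

test_that("planted nonsense mutations reach the report at exact positions", {
  r <- run_sim_study(sim_params(seed = 42, subst_rate = 0,
                                planted_events = list(
    list(branch = "Hsa", kind = "pseudogenization",
         recipe = list(nonsense = 2)))))
  expect_equal(unname(r$report$verdicts[["Hsa"]]), "Pseudogene")
  got <- r$report$mutation_reports$Hsa
  want <- expected_report(r$sim$ledger)$mutations$Hsa
  expect_setequal(mutation_key(got), mutation_key(want))
  expect_true(all(got$branch == "Hsa"))
  ev <- r$report$events$events
  expect_equal(ev$event[ev$branch == "Hsa"], "pseudogenization")
})

test_that("an intact but unannotated gene is rescued as Saved", {
  r <- run_sim_study(sim_params(seed = 43, unannotated_species = "Mmu"))
  expect_equal(unname(r$report$verdicts[["Mmu"]]), "Saved")
  # saved verdict carries a prediction in the evidence chain
  expect_false(is.null(r$report$evidence$Mmu$prediction))
})

test_that("simple mode reports Lost for every missing species", {
  r <- run_sim_study(sim_params(seed = 44, planted_events = list(
    list(branch = "Hpa", kind = "pseudogenization",
         recipe = list(nonsense = 1)))), mode = "simple")
  expect_equal(unname(r$report$verdicts[["Hsa"]]), "Lost")
  expect_equal(unname(r$report$verdicts[["Ptr"]]), "Lost")
  expect_equal(r$report$events$events$branch, "Hpa")
})

test_that("verdicts partition the studied species", {
  r <- run_sim_study(sim_params(seed = 45, planted_events = list(
    list(branch = "Mmu", kind = "pseudogenization",
         recipe = list(splice_donor = 1)),
    list(branch = "Rno", kind = "loss")),
    unannotated_species = "Ppy"), query_species = "Mdo", ancestor = "The")
  v <- r$report$verdicts
  expect_setequal(names(v), species_under(r$sim$tree, "The"))
  expect_true(all(v %in% c("Present", "Saved", "Pseudogene", "Lost",
                           "Unresolved")))
})

test_that("excluding an annotated gene forces its re-annotation", {
  sim <- simulate_family(sim_params(seed = 46))
  # drop the human protein from the proteome but keep genome + annotation:
  # without exclusion the locus is recognised as the annotated gene
  prot <- sim$proteome[sim$proteome$species != "Hsa", ]
  class(prot) <- c("seq_records", "data.frame")
  cfg <- run_config("Eth", seed = 46)
  q <- prot$id[prot$species == "Mus"][1L]
  rep1 <- run_study(q, prot, sim$tree, cfg, sim$genomes, sim$annotations)
  expect_equal(unname(rep1$verdicts[["Hsa"]]), "Present")
  expect_equal(rep1$evidence$Hsa$annotated_gene, "g1")
  # with the annotation excluded the study must re-derive the verdict
  cfg2 <- run_config("Eth", seed = 46, excluded_gene_ids = "g1")
  rep2 <- run_study(q, prot, sim$tree, cfg2, sim$genomes, sim$annotations)
  expect_equal(unname(rep2$verdicts[["Hsa"]]), "Saved")
})

test_that("batches isolate failures and preserve determinism", {
  sim <- simulate_family(sim_params(seed = 47))
  q <- sim$proteome$id[sim$proteome$species == "Mus"][1L]
  good <- list(query = q, proteome = sim$proteome, tree = sim$tree,
               config = run_config("Eth", seed = 47),
               genomes = sim$genomes, annotations = sim$annotations)
  bad <- good; bad$config <- run_config("NotANode", seed = 47)
  out <- run_batch(list(good, bad))
  expect_s3_class(out[[1L]], "study_report")
  expect_match(out[[2L]]$error, "NotANode")
  expect_length(run_batch(list()), 0L)
  # same study twice: identical reports
  out2 <- run_batch(list(good, good))
  expect_identical(report_json_string(out2[[1L]]),
                   report_json_string(out2[[2L]]))
})

test_that("the JSON report and annotated tree serialise a full study", {
  r <- run_sim_study(sim_params(seed = 48, subst_rate = 0,
                                planted_events = list(
    list(branch = "Hpa", kind = "pseudogenization",
         recipe = list(nonsense = 1)))))
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(r$report, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$verdicts$Hsa, "Pseudogene")
  expect_equal(parsed$events[[1L]]$branch, "Hpa")
  expect_gte(length(parsed$events[[1L]]$mutations), 1L)
  nhx <- withr::local_tempfile(fileext = ".nhx")
  write_annotated_tree(r$sim$tree, r$report, nhx)
  tags <- read_annotated_tree(nhx)$tags
  expect_equal(tags$Hsa[["S"]], "Pseudogene")
  expect_match(tags$Hpa[["EV"]], "pseudogenization")
  expect_match(tags$Hpa[["MUT"]], "nonsense")
})

test_that("the sub-family scan reports per-subfamily missing species", {
  set.seed(60)
  aas <- names(lineageloss:::PREFERRED_CODON)
  base <- paste(sample(aas, 100, TRUE), collapse = "")
  mutate <- function(s, n) {
    v <- strsplit(s, "")[[1L]]
    idx <- sample(length(v), n)
    v[idx] <- sample(aas, n, TRUE)
    paste(v, collapse = "")
  }
  copy2 <- mutate(base, 30)           # a diverged paralog sub-family
  prot <- seq_records(
    c("Hsa|a1", "Mus|a1", "Mdo|a1", "Hsa|a2", "Mus|a2"),
    c(mutate(base, 2), mutate(base, 3), mutate(base, 4),
      mutate(copy2, 2), mutate(copy2, 3)),
    "protein")
  tr <- tree8()
  cfg <- run_config("The", mode = "simple", scan_subfamilies = TRUE,
                    seed = 60)
  rep <- run_study("Mus|a1", prot, tr, cfg)
  expect_false(is.null(rep$subfamily_scan))
  expect_gte(length(rep$subfamily_scan), 1L)
  sf <- rep$subfamily_scan[[length(rep$subfamily_scan)]]
  expect_true("Mus|a1" %in% sf$members)
  member_sp <- unique(sub("\\|.*$", "", sf$members))
  expect_length(intersect(sf$missing, member_sp), 0L)
  expect_setequal(c(member_sp, sf$missing),
                  species_under(tr, sf$mapped_ancestor))
  # scan disabled by default
  cfg2 <- run_config("The", mode = "simple", seed = 60)
  expect_null(run_study("Mus|a1", prot, tr, cfg2)$subfamily_scan)
})
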