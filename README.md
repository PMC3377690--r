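# lineageloss

Detection and forensic analysis of lineage-specific gene losses and unitary
pseudogenes from proteomes, genomes and a dated species tree.

## The problem

A well-established ancestral gene normally leaves at least one descendant
copy in every species of a clade. Occasionally all representatives vanish in
one lineage — either by outright deletion of the locus or by
*pseudogenization*: a disabling mutation (a premature stop, a frameshifting
indel, a broken splice site, a lost exon) inactivates the only copy, which
then erodes neutrally. Such *unitary pseudogenes* (the primate vitamin-C
pathway is the textbook case) mark relaxed or reversed selection and are
easy to miss: annotation pipelines drop them, and absence from an annotation
set is weak evidence of absence from a genome.

`lineageloss` automates the whole investigation for one query protein at a
time:

1. **Phylogenetic screen.** Homologs of the query are collected from the
   proteomes, a gene tree is built (pairwise global alignments, `-ln(1-p)`
   distances, neighbor joining), rooted to minimise duplications, and
   reconciled with the species tree by LCA mapping. The ortholog group at a
   chosen ancestor is read off the reconciled tree; species of the clade
   with no member are loss candidates.
2. **Genome rescue.** For each candidate species the genome is scanned with
   a six-frame seed-and-extend translated search using the closest
   ortholog as reference; compatible hits are chained into locus candidates,
   confirmed orthologous by re-building the gene tree, and a best protein is
   predicted by intron-aware spliced alignment (GT..AG, stop-avoiding).
   Already-annotated genes at the locus resolve the case immediately.
3. **Verdict.** Strong signals go to a nucleotide-level study: the loci are
   multiple-aligned, compacted to the exon projection of an annotated
   reference, ancestral sequences are reconstructed by Sankoff parsimony,
   and every branch from the deepest ancestor to the candidate is scanned
   codon-by-codon for nonsense codons, indels/frameshifts, splice-site edits
   and exon losses. Weak signals fall back to a protein-level conservation
   test: in the calibrated geometry the candidate passes when its identity
   `Value1` to a known ortholog exceeds the threshold `D2 x Value2 / D1`
   built from the divergence times and identity of a known pair.
4. **Synthesis.** Per-species verdicts (Present / Saved / Pseudogene /
   Lost) are combined on the species tree by Dollo-like (simple mode) or
   Sankoff (complete mode) parsimony, yielding the gene-birth node and
   branch-placed loss and pseudogenization events, each decorated with its
   supporting mutations.

A seeded simulator (`simulate_family`, `random_scenario`) generates complete
synthetic inputs — genomes, proteomes, exon annotations — with planted
losses and pseudogenizations and a machine-readable truth ledger, and is the
basis of the validation suite.

## Worked example

```r
library(lineageloss)

# a synthetic family: pseudogenization (2 nonsense codons) before the
# human/chimp split, gene loss in macaque
p <- sim_params(seed = 7, planted_events = list(
  list(branch = "Hpa", kind = "pseudogenization",
       recipe = list(nonsense = 2)),
  list(branch = "Mmu", kind = "loss")))
sim <- simulate_family(p)

cfg <- run_config(ancestor = "Eth", mode = "complete", seed = 7)
rep <- run_study("Mus|g1", sim$proteome, sim$tree, cfg,
                 genomes = sim$genomes, annotations = sim$annotations)
summary(rep)
```

```
Lineage-loss study of Mus|g1 under ancestor Eth (complete mode)
Verdicts: Present=4 Saved=0 Pseudogene=2 Lost=1 Unresolved=0
Gene birth at: The
  gene_loss on branch Mmu
  pseudogenization on branch Hpa
Mutations on the Hsa lineage:
 branch     kind exon position detail
    Hpa nonsense    3       16    TAA
    Hpa nonsense    3       18    TAA
    Hpa nonsense    4       14    TAG
Mutations on the Ptr lineage:
 branch     kind exon position detail
    Hpa nonsense    3       16    TAA
    Hpa nonsense    3       18    TAA
    Hpa nonsense    4       14    TAG
```

The two planted stop codons (`TAA`, exon 3) are recovered at their exact
codon positions and attributed to the `Hpa` stem branch — they are shared
by human and chimp, so they predate the split. The third stop (`TAG`,
exon 4) is a background substitution that accumulated on the same branch
after inactivation, exactly what a decaying pseudogene does; the macaque
deletion appears as a `gene_loss` on the `Mmu` terminal branch. `write_report_json()` and
`write_annotated_tree()` serialise the study as JSON and as an NHX-tagged
Newick tree.

A thin command-line wrapper for file-based runs is installed under
`inst/scripts/lineageloss-cli.R` (subcommands `run`, `simulate`, `batch`).

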