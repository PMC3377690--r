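---
title: "Detecting lineage-specific gene loss and unitary pseudogenes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific gene loss and unitary pseudogenes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineageloss)
```

## The question and the overall procedure

Given one query protein, a set of proteomes and genomes, and a rooted,
binary, ultrametric species tree with branch lengths in million years (MY),
`lineageloss` decides, for every species descending from a chosen ancestor,
whether a representative of the query's gene family is **Present** in the
annotation set, **Saved** (intact in the genome but missing from the
annotations), a **Pseudogene** (recognisable but disabled), or **Lost**
(no orthologous signal in the genome), and then places the implied
loss/pseudogenization events, and the gene's birth, on branches of the
species tree.

The species tree is the fixed coordinate system of the analysis. It must be
ultrametric because the protein-level conservation test calibrates an
expected identity decay against divergence *ages*; a non-ultrametric tree
is rejected (relative tolerance `1e-6` of the root depth) rather than
silently normalised, since the calibration would be meaningless.

### Phase 1 — orthology screen

Homologs of the query are gathered from the proteomes by global alignment
(at least 30 % identity to the query, up to 3 genes per species; both
configurable). Pairwise distances are `-ln(1 - p)` with `p` the mismatch
fraction over mutually ungapped columns of the pairwise global alignment;
pairs at `p >= 0.95` are capped with a warning, since the transform
diverges. A neighbor-joining tree (Saitou–Nei Q criterion) is built, rooted
on the edge minimising the number of inferred duplications after
reconciliation, and reconciled with the species tree by LCA mapping: a
gene-tree node is a *duplication* exactly when its mapping equals a child's
mapping.

The ortholog group of the query at the chosen ancestor is the leaf set of a
speciation node on the query-to-root path whose mapping lies at or below
the ancestor; among qualifying nodes the one whose mapping is oldest (and,
among equals, nearest the root) defines the group — this formalises "use
the next speciation node towards the leaves when none maps exactly to the
ancestor". Species of the clade absent from the group are loss candidates.
An optional scan enumerates sub-family roots (speciation nodes directly
under a duplication on the query path) so each newly established sub-family
can be studied separately.

Distance/NJ trees stand in for a maximum-likelihood phylogeny pipeline
here; the downstream logic consumes only labelled topologies, and NJ on the
p-distance transform is consistent on the additive distances the simulator
produces. This substitution, and the absence of bootstrap filtering, are
deliberate scope choices: trees are treated as point estimates.

### Phase 2 — genome rescue

For each candidate species, the reference is the group ortholog from the
species with the smallest divergence time to the candidate. The genome is
scanned by a built-in translated search: exact protein k-mer seeds
(k = 4) against all six reading frames, seed groups extended by local
affine-gap alignment (BLOSUM62, gap open 11, extend 1); stop codons score
as strong mismatches but do not terminate extension, because a pseudogene's
reading frame is exactly what we are looking for. Hits at or above 50
matrix units (configurable) are chained greedily when they share a
chromosome and strand, are collinear in genome and protein, lie within
50 kb of each other (a generous intron allowance), and overlap by at most
5 aa in protein coverage. No e-value statistics are computed; ranking is by
raw score, which is all the downstream logic needs.

Each chained candidate is re-tested for orthology by inserting its
translated hit concatenation into the gene-tree construction; a candidate
is accepted when its extracted ortholog group contains at least one member
of the original group. At most 5 candidates are tried per species before
concluding Lost. The locus (hit span plus 5 kb flanks, clamped to the
chromosome) is extracted in transcript orientation, and a best protein is
predicted by a spliced-alignment dynamic program: local in both sequences,
introns enterable only at codon boundaries with canonical GT..AG termini
and at least 20 nt length, stop codons excluded from exons so the optimum
must shorten, splice around, or shift past them. A prediction is kept when
its score reaches 40 % of the reference self-score — deliberately
permissive, because degraded pseudogene loci still need a best protein for
the depth gate. No start codon is required at prediction time; start loss
is the scanner's job, not the predictor's.

If an annotation (not on the exclusion list) already overlaps the locus,
the species is Present and the new orthology is recorded as a report
annotation. The exclusion list is how suspicious annotations are
re-analysed: relaunching with the gene id excluded forces the locus to be
re-derived from the genome alone.

### The depth gate and the protein-level test

The translated-hit protein *and* the prediction are both compared to the
reference (both, because nonsense codons shorten predictions but barely
affect translated hits). If either reaches 50 % identity and 60 % length
ratio (identity over the full alignment length including gap columns;
length ratio against the reference length), the study proceeds at the
nucleotide level; otherwise the verdict comes from the protein-level
conservation test:

* **Distinct-LCA geometry** — two known orthologs have different LCAs with
  the candidate: the candidate passes when it is more similar to its nearer
  known than the wider known pair are to each other.
* **Same-LCA geometry** — all knowns share one LCA with the candidate: with
  `D1` the candidate-pair age, `D2` and `Value2` the age and identity of
  the most divergent known pair, the threshold is `D2 * Value2 / D1`, and
  the candidate passes when its identity `Value1` exceeds it. The verdict
  is invariant under rescaling both ages, and monotone in `Value1`.

Reading the denominator as `D1` is an interpretation: the published legend
names a "distance D" it never defines; dividing by `D1` is the only reading
that reduces the threshold to `Value2` when the two pairs coincide, so that
is what is implemented, and the report always carries `D1`, `D2`,
`Value1`, `Value2` and the threshold for audit.

### Phase 3 — nucleotide forensics

All candidates that pass the gate are studied **together**: one sequence
per species (the most reference-similar), known orthologs dropped when
their protein identity falls below `100 - 60 = 40 %` (the
`test3_max_divergence_pct` default), and at least 3 sequences required —
otherwise the study falls back to the protein-level verdict.

The loci are multiple-aligned by a progressive profile aligner (UPGMA guide
on shared 8-mer distances, banded affine profile alignment, free end gaps
for the ragged flanks) and *compacted*: only columns inside the projection
of an annotated reference's exons, plus 20 nt of intron context per
junction, are kept. The 20 nt default retains the GT/AG dinucleotides plus
context; the compaction exists to cut alignment noise and computation, not
to change the science. Ancestral rows for every internal node are
reconstructed by per-column Sankoff parsimony over `{A,C,G,T,-}` with unit
substitution and gap-transition costs, ambiguities resolved preorder
preferring the parent state, then alphabetical order. The guide tree is by
default an NJ tree on TN93 distances over the compacted columns
(closed-form TN93 approximating an HKY-style correction), with the pruned
species tree available as a forced alternative — the pipeline forces the
species tree so that mutation branches are species-tree branches. A
parsimony reconstruction with explicit gap states stands in for a
stochastic-graph ancestral reconstructor; it preserves the contract the
scanner needs (an explicit ancestor per node, indels readable as gap-state
changes per branch), at the price that insertion-vs-deletion polarity on
deep branches rests on parsimony rather than an indel model.

Every branch from the root of the reconstruction tree to each candidate is
scanned in the projected reading frame of the reference:

* **nonsense** — the descendant gains an in-frame stop the ancestor lacks;
* **insertion / deletion** — a gap run present in one row only, with a
  companion **frameshift** when the length is not a multiple of 3 (the
  frameshift is an annotation of the causal indel, not an independent
  event); indel positions are canonicalised by left alignment so repeated
  context cannot shift the reported offset;
* **start_loss / stop_loss** — at the projected initiator/terminator;
* **splice_donor / splice_acceptor** — a canonical GT/AG in the retained
  flank altered relative to the ancestor; junctions flanking a lost exon
  are silent, since they carry no splice information;
* **exon_loss** — a projected exon at least 90 % gap in the descendant but
  under 50 % gap in the ancestor (the two thresholds are design constants;
  a lost exon also suppresses codon-level scanning within it).

A mutation found on an ancestor-vs-ancestor comparison is attributed to
that internal branch, so an event shared by sister species is reported
once, on their stem. A sequence is a pseudogene iff its lineage carries at
least one disabling mutation; in-frame indels alone do not condemn. A
projection-quality guard flags exons whose boundaries align to gaps in at
least half of the other rows as low-confidence, because a misprojected
exon boundary can silently shift the scanned frame — the report surfaces
the flag rather than trusting the scan.

### Synthesis

Verdicts map to three ancestral states (Saved counts as Gene — it is a
provenance flag, not a biological state) and Sankoff parsimony with an
irreversible cost matrix (Gene→Pseudogene, Gene→Absent,
Pseudogene→Absent at cost 1; reverse transitions infinite; a Lost leaf
under a Pseudogene ancestor is erosion to undetectability, cost 1) assigns
ancestral states; ties prefer Gene, then Pseudogene. Events sit exactly on
state-change branches, the birth is the highest Gene node, and
pseudogenization branches carry their supporting mutations. Simple mode
(annotation-only surveys, old losses) skips the genome work entirely and
uses Dollo-like parsimony: birth at the LCA of the present species, one
loss on the stem of every maximal absent clade. A single birth is enforced
by construction.

## The simulator: what it emulates, and what it does not

`simulate_family()` builds a root gene — a preferred-codon back-translation
of a random protein with ATG start, TAA terminator and GT..AG phase-0
introns (defaults: exons of 120/150/90/141 nt, introns of 150/200/180 nt)
— embeds it in 2 kb of random intergenic DNA per side, and evolves the
whole chromosome down the tree with binomially drawn per-branch
substitution counts at a default 0.05 substitutions/site/100 MY (a
conserved-gene figure: it puts human–mouse DNA identity near 90 %) with a
2:1 transition:transversion ratio. Planted events are applied on their
branches and inherited below: losses excise the gene region;
pseudogenization recipes plant nonsense codons, indels, splice edits, exon
losses and start/stop losses at recorded positions, at least 12 nt from
exon boundaries unless a splice site is the target, and withdraw the
species from the proteome. Background substitutions never create or
destroy a stop, the initiator, the terminator or a splice dinucleotide in
an intact gene, and planted positions are frozen thereafter — this is what
makes the truth ledger the *deterministic* consequence of the planted
events, so expected verdicts and mutation inventories are exactly
comparable. Pseudogenized lineages, by contrast, accumulate unconstrained
background mutations, as real pseudogenes do; recovered inventories may
therefore contain genuine extra events beyond the recipe.

What the simulator does **not** emulate — and what green tests therefore do
not establish about real data: codon-usage and rate heterogeneity,
segmental duplication and gene conversion, non-canonical and phase-1/2
splice sites (the spliced aligner models phase-0 introns only; real genes
split codons across junctions), assembly gaps and sequencing error,
polymorphic pseudogenes, and annotation noise beyond complete omission.
Transfer to real genomes rests on the component contracts (alignment
scores, parsimony optimality, search sensitivity), which are tested against
independent oracles, not on the simulator's realism.

## Numerical and determinism choices

* All alignments resolve traceback ties in a fixed operator order
  (diagonal > up > left); gap runs of length L cost `open + L * ext`.
  Protein scoring is BLOSUM62 (gap 10/0.5 for global comparisons, 11/1 for
  search extension); locus alignment uses +2/−2 with N neutral, gap 6/1.
* NJ joins the lexicographically smallest label pair among Q-minima;
  Sankoff ties prefer the parent state then alphabetical order; the
  synthesis prefers Gene, then Pseudogene. Everything downstream of a seed
  is bit-reproducible; a study rerun with the same seed yields
  byte-identical JSON.
* Degenerate inputs have defined behaviour: empty hit lists are a Lost
  verdict, not an error; an unpredictable locus is a valid none; fewer
  than 3 reconstruction taxa falls back to the protein test; per-species
  failures become an Unresolved verdict with a warning instead of
  aborting the study.
* Coordinates are 0-based half-open internally and 1-based closed in all
  human-readable output; minus-strand features are stored in plus-strand
  coordinates with a strand flag and extracted in transcript orientation.

## Validation problem sizes

The test suite checks the alignment kernel against exhaustive enumeration
(pairs up to length 6) and against an independent Needleman–Wunsch
implementation (1,000 random pairs up to length 12); NJ against 100 seeded
additive matrices of 4–12 taxa; reconciliation against an independent LCA
recomputation on 200 random gene trees; Sankoff against exhaustive
enumeration on all 81 leaf labelings of a 4-leaf tree and 500 seeded
labelings of an 8-leaf tree; the forensic scan on 20 noise-free scenarios
(exact kind/exon/position/branch) and 20 noisy scenarios at 0.03
substitutions/site/100 MY, which keeps every branch at or below 0.05
substitutions/site; and the full pipeline on 20 mixed and 20 event-free
studies on the nine-species example tree. These sizes were chosen as the
smallest that exercise every code path and tie-break; `scripts/acceptance.R`
recomputes the same quantities from scratch.

## Known limitations

* Intron phase: predictions and planted genes are phase-0 only.
* Gene trees are NJ point estimates without support values; a weakly
  supported topology can misplace the ortholog group boundary.
* Insertion/deletion polarity on deep branches follows parsimony, which
  can differ from a probabilistic indel model.
* The exon-loss thresholds (90 % / 50 %) and the search score threshold are
  pragmatic constants, exposed in the configuration.
* Selection-based confirmation (dN/dS) and transcript evidence are out of
  scope; verdicts are sequence-forensic only.
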