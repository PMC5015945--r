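---
title: "Methods: lincRNA emergence, duplication, loss and decay across a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lincRNA emergence, duplication, loss and decay across a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long intergenic noncoding RNAs (lincRNAs) are annotated by the thousands in
plant genomes, but most lack detectable homologs outside the annotating
species. Whether a given locus is young, rapidly diverging, or simply lost
in other lineages cannot be read off a single genome. `lincphylo`
implements a comparative pipeline that takes a focal species' lincRNA
annotation plus a panel of related genomes on a dated phylogeny and asks,
for every locus: in which species does a homologous locus survive, when did
the locus emerge, has it duplicated, and — where it is missing — was it
deleted outright (*loss*) or is it still present but diverged beyond the
strict detection threshold (*decay*)?

Because no public genome panel ships with ground truth, the package also
contains a generative model (`simulate_lincrna_cohort()`) that plants loci
with known birth nodes, duplication events, losses, decay switches,
transposable-element (TE) insertions and conserved noncoding sequence (CNS)
islands into synthetic genomes, so that every pipeline stage can be scored
against a complete truth table.

## Homology: seeded search, reciprocity, synteny

The search engine (`search_genome()`) is a classic seeded local aligner:
exact 8-mer seeds on both strands, ungapped X-drop extension (X = 20), and
an affine-gap Smith–Waterman polish of candidate regions (match +1,
mismatch −2, gap open 5, gap extend 2, costs). Significance uses
Karlin–Altschul statistics `E = K·m·n·e^{−λS}` with the ungapped λ solved
for the +1/−2 scheme under uniform base frequencies and `K = 0.46` as a
fixed calibration constant. For alignments where both the query and the
candidate window exceed a few hundred bases the polish is banded (±128
diagonals around the seeded diagonal, widened by the length difference);
small problems are solved in full, which is what the test-suite oracle
checks exactly.

A hit becomes a *homolog* only if it clears three bars (`call_homologs()`):

* **sequence similarity** — E ≤ 1e−20 (`strict_evalue`); hits on the same
  chromosome and strand closer together than the query length are merged
  first (`merge_hits()`), and only the top hit per species is considered;
* **reciprocity** — the subject sequence, searched back against the focal
  genome at the same strict cutoff, must return a top hit overlapping the
  original query locus by ≥ 1 bp. A back-search that prefers a paralogous
  copy (for instance a tandem duplicate 1.5 kb away) fails this test; that
  is deliberate and mirrors top-hit reciprocal-best-hit practice, and it is
  the dominant source of missed homolog calls in simulations with frequent
  local duplication;
* **synteny** — at least one of the two flanking protein-coding anchor
  genes (or a 5-kb flank where genes are absent) must have its top hit on
  the same chromosome within `synteny_window_bp` (50 kb by default; the
  underlying decision rule has no canonical threshold, so this is exposed
  in the configuration).

Anchor genes are searched at the relaxed cutoff (1e−5) because the
loss/decay stage must still find anchors whose neighborhoods are decaying;
using one anchor search for both stages keeps the two classifications
consistent.

## Families, conservation depth and coding filters

`build_families()` groups each query with its promoted homologs (at most
one per species). Intervals contested by several families go to the family
with the lowest E-value (ties: higher score, then query id) — the rule
itself is a package choice since only uniqueness, not the tie-break, is
canonical. A family is **conserved** when it has members from at least
four species (including the focal one) with at least one member from
lineage II, i.e. the locus must straddle the deepest split (~42 Myr) of
the core ingroup. Conservation **depth** is the age of the most recent
common ancestor of the focal species and the most divergent member.

Two filters guard against protein-coding contamination:

* `orf_screen()` rejects queries carrying an open reading frame longer
  than 100 amino acids (ATG…stop, either strand; exactly 100 aa does not
  trigger).
* `conserved_coding_test()` is a permutation test for cross-species
  reading-frame preservation. Members are first projected onto ungapped
  query coordinates (`family_alignment()`: each member is globally aligned
  to the query with free end gaps and stacked; insertions relative to the
  query are dropped — a deterministic, star-shaped substitute for a
  multiple aligner, justified because families are star-shaped around the
  query by construction). Over the best of the three reading frames the
  statistic `T = #synonymous − #nonsynonymous − 3·(#frameshifting gaps +
  #in-frame stops)` is compared with its distribution under column
  shuffling (1000 permutations); families with `p < 0.001` are flagged.
  The test claims planted-signal recovery only — it is not a reimplementation
  of any phylogenetic codon model, and it is applied only to alignments
  with at least four sequences.

## Gene trees and duplication dating

For each conserved family the pipeline builds a multi-copy alignment: the
query, each species' member, and up to two further strict, non-overlapping
hits per species (paralogs), including extra copies found in the focal
genome itself. Without these extra leaves an LCA reconciliation could not
place duplications at internal nodes, since single-copy trees are almost
always congruent.

Trees are inferred by neighbor joining on Jukes–Cantor distances
(gap/ambiguous columns dropped; saturation capped at `d = 5`), with
supports from 100 column-resampling bootstrap replicates. The JC+NJ
combination replaces maximum-likelihood inference; it is consistent on
additive distances, deterministic (Q-criterion ties break by lowest index
pair), and fast enough to bootstrap thousands of families. The
alignment→tree step is isolated behind `bootstrap_supports()`, so a
different tree builder can be substituted without touching reconciliation.

`reconcile()` then: (1) collapses internal branches with support < 70%
into polytomies; (2) enumerates every rooting of the resulting unrooted
tree; (3) resolves polytomies optimally — the duplication/loss cost of a
polytomy depends only on its own resolution, so each polytomy is solved
independently by exhaustive enumeration of its (2k−3)!! joinings for up to
six children, with a species-guided greedy fallback above that (greedy
joining is standard here; exact local enumeration is strictly better and
lets the test suite demand exact agreement with a global brute-force
oracle); (4) keeps the rooting minimizing duplications, then losses, then
a canonical newick string, guaranteeing determinism. Events follow the LCA
mapping: node `v` is a duplication iff `M(v)` equals a child's mapping;
each child edge contributes `depth(M(child)) − depth(M(v))` skipped
species-tree edges as losses, minus one at speciation nodes.

`summarize_duplications()` drops families with more than three
duplications on the root→focal backbone and bins the remaining events by
backbone node. When judging recovery of *planted* events, the fair target
is not the planted node itself but the LCA of the species in which both
daughter lineages survive (`expected_duplication_nodes()`); fractionation
after whole-genome duplication routinely prunes one side of an event down
to a single species, and a correct reconciliation then maps the event to
that shallower node.

## Loss versus decay

For a conserved family and a species with no strict homolog,
`classify_loss_decay()` re-searches the query and the focal anchor genes
at the relaxed 1e−5 cutoff. The species is scored **decayed** iff a
relaxed query hit lies on the same chromosome as an anchor-gene hit within
the effective linkage distance `max(10 kb, observed focal query-to-anchor
distance)`; otherwise **lost**. Per-species proportions are compared with
pairwise binomial score tests under a Bonferroni correction
(`proportion_score_test()`, `group_species()`); species whose corrected
tests are non-significant are linked, and groups are the connected
components of that graph. Components are used rather than cliques because
the grouping procedure is underspecified in the underlying method;
non-clique components are flagged in the output.

## The generator and what it does (not) emulate

`sim_params()` defaults define the study conditions:

| parameter | default | meaning |
|---|---|---|
| tree | 11-taxon chronogram | ages 13/18/30/42/54/65 Myr; lineage II splits at 35/25/20; focal `Ath` |
| `n_loci`, `locus_len` | 200 / 400 nt | ancestral loci planted at backbone nodes |
| `birth_weights` | 0.30 at age 0 … 0.08 at 65 | ~30% focal-specific, ~30% born at/above the lineage split |
| `subst_rate` | 0.002 subst/site/Myr | neutral intergenic scale; JC with uniform bases, so divergence has a closed form |
| `indel_rate` | 0.1 | indel events per substitution event, lengths 1–5 nt |
| `loss_prob`, `decay_prob` | 0.02 each per branch | deletion / switch to hyper-mutation |
| `decay_multiplier` | 8× | rate multiplier in decay mode (a tuning choice; no empirical estimate exists) |
| `dup_prob` | 0.05 per branch | local duplication, forking at a uniform point within the branch |
| WGD | `Bra`∧`Bol` node and `Lal` branch | copies double on the stem branch; each copy retained with probability 0.65 |
| `cns_len`, `cns_rate_multiplier` | 36 nt, 0.05× | CNS island inside 80% of deep-born / 25% of shallow-born loci |
| `te_insert_prob` | 0.15 | TEs inserted in/near shallow-born focal loci only |
| expression / stress | log₁₀FPKM ~ N(−0.5 + 0.01·age, 0.4); logit P(stress) = −2.4 + 0.035·age | covariates increasing with birth age, matching the observed ~8.5%→~49% stress gradient |

Two timing choices matter for identifiability. Whole-genome duplications
double copy number on the *stem branch* of the flagged node, so copy
divergence predates the clade's crown split — a WGD placed exactly at a
node would make copy and species splits simultaneous and the resulting
quartets unresolvable by any distance method. Local duplications fork at a
uniformly drawn point inside their branch for the same reason.

The generator emulates: branch-length-proportional JC divergence (with a
closed-form calibration via `expected_divergence()`), short indels kept
out of CNS islands, collinear anchor genes (synteny is intact by default;
`synteny_break_prob` can translocate loci), tandem placement of duplicate
copies 1.5 kb from the primary copy, TE insertions that never interrupt
CNS islands, and depth-correlated expression/stress covariates. It does
not emulate: genome-scale repeat landscapes, realistic TE families,
recombination, codon structure, rate heterogeneity across sites, or
chromosomal rearrangement beyond optional single-locus translocation.
Passing tests therefore demonstrate method correctness under a idealized
neutral-divergence model, not performance on real genomes — in particular
real search sensitivity depends on repeat masking and alignment heuristics
that the engine simplifies.

## Numerical choices and degenerate inputs

* Ns never match in alignment scoring; columns containing gaps or Ns are
  excluded from distances.
* Bootstrap supports count a bipartition only when its internal branch has
  positive length, so alignments without signal give 0, not 100.
* `jc_distance()` caps saturated pairs (`p ≥ 0.75`) at 5 substitutions/site.
* The binomial score test returns `z = 0, p = 1` when the pooled
  proportion is degenerate; Fisher's odds ratio is reported as the sample
  `ad/bc` with the usual 0/∞ conventions.
* All stochastic stages draw from streams keyed by `(seed, stage name)`
  (`lincphylo_config(rng_seed=)`), so individual stages are reproducible
  in isolation.
* log-FPKM uses a 0.01 pseudocount; the source data are plotted on a log
  scale without a stated transform, so the pseudocount is a package choice.

## Problem sizes

The shipped test-suite and the acceptance script use cohorts of 15–60 loci
for unit-level checks, 200 loci for process calibration (binomial CIs on
loss/duplication frequencies checked against 99% binomial intervals and a 3σ check of
realized divergence), and one 500-locus, 11-genome cohort for end-to-end
planted-history recovery; these sizes give the statistical power the
claims need while keeping a full run in the minutes range on one core.
The exhaustive reconciliation oracle covers every unrooted topology with
up to six leaves under representative multi-copy species assignments.

## Known limitations

* Reciprocity is judged on the single top back-hit; tandem arrays can
  therefore fail promotion even when a co-ortholog is present (measured at
  roughly a tenth of homolog pairs under the default duplication rate).
* The decay window is bounded: a locus that decays for long enough falls
  below even the relaxed threshold and is indistinguishable from loss;
  conversely decay over a short terminal branch may still clear the strict
  threshold and be scored present. The loss/decay truth-table accuracy
  reported by `evaluate_recovery()` quantifies the combined effect.
* Statistical power of the species grouping depends on the number of
  conserved families; with ~100–150 families, loss-rate differences of
  ten percentage points sit at or below the Bonferroni-corrected
  detection limit (the weakest pairwise score test between a
  whole-genome-duplication lineage and a non-duplicated one has an
  expected z around 3–3.5 against a critical value near 3.6), so
  isolating the WGD lineages reliably needs cohorts of a few thousand
  loci even when every planted loss is classified correctly.
* Duplication-node dating by the JC+NJ+bootstrap route recovers planted
  nodes for roughly nine of ten reconciled events; most residual errors
  place an event one node too deep, caused by weakly wrong gene-tree
  joins that clear the 70% support threshold. The reconciliation step
  itself is exact (it matches a brute-force oracle in the test suite);
  the noise is in tree inference on short alignments.
* The miRNA expectation score is an ungapped sliding-window
  implementation of the published scoring conventions (seed-doubled
  penalties, G:U = 0.5, cutoff 2.0 over 20 nt); bulged target sites are
  not modeled.
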