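# lincphylo

Comparative-genomic analysis of long intergenic noncoding RNA (lincRNA)
loci across a dated species phylogeny: where each locus has detectable
homologs, when it emerged, whether it duplicated, and — where it is
missing — whether it was deleted (*loss*) or has diverged beyond
recognition in place (*decay*).

`lincphylo` is aimed at plant comparative genomicists working with a
well-annotated focal species (an *Arabidopsis*-like setting) and a panel
of related genomes spanning two major lineages. It implements the whole
chain as tested, composable R functions:

* a seeded local-alignment **homology search** (word size 8, match +1 /
  mismatch −2, gap open 5 / extend 2) with Karlin–Altschul E-values
  (`E = K·m·n·e^{−λS}`), hit merging, strict top-hit selection
  (E ≤ 1e−20), reciprocal-best-hit verification, and synteny checks
  against the nearest flanking protein-coding genes (or 5-kb flanks);
* **family construction** with a two-lineage conservation criterion
  (≥ 4 species including ≥ 1 lineage-II member), conservation-depth
  assignment (MRCA age of the most divergent member), an ORF screen
  (> 100 aa disqualifies), and a permutation test for conserved
  reading frames;
* **gene trees and duplication dating**: neighbor joining on
  Jukes–Cantor distances, 100 bootstrap replicates, collapse of branches
  under 70% support, exhaustive rooting, and LCA-mapping reconciliation
  with the species tree (duplications dated by their mapped node;
  families with > 3 backbone duplications excluded from summaries);
* **loss-vs-decay classification** at a relaxed cutoff (1e−5) with the
  10-kb syntenic-linkage rule, pairwise binomial score tests and
  Bonferroni-corrected species grouping;
* **conservation correlates**: TE overlap classes (≥ 10 nt inside /
  within 100 bp / within 500 bp), CNS overlap, expression–depth
  regression and Pearson correlation, stress-responsiveness by depth with
  Fisher's exact tests, psRNATarget-convention miRNA expectation scores
  (cutoff 2.0 over 20 nt), and a Nussinov base-pairing folding proxy;
* a **synthetic-cohort generator** that plants known evolutionary
  histories (birth node, Jukes–Cantor divergence, indels, local and
  whole-genome duplications with fractionation, loss, 8× decay, TEs, CNS
  islands, covariates) into multi-species genomes with a complete truth
  table, so every stage above can be scored against ground truth.

## Worked example

Simulate a small cohort on the default 11-taxon chronogram, run the
pipeline, and compare with the planted truth:

```r
library(lincphylo)

sim  <- simulate_lincrna_cohort(sim_params(n_loci = 60, rng_seed = 7))
pipe <- run_pipeline(sim, lincphylo_config(rng_seed = 7))
pipe
#> linc_pipeline: 59 families ( 16 conserved ), 128 loss/decay calls

evaluate_recovery(pipe, sim) |> as.data.frame()
#>   homolog_recall_pct homolog_precision_pct conserved_agreement_pct
#> 1           98.18182                   100                     100
#>   loss_decay_accuracy_pct duplication_node_accuracy_pct ...
#> 1                96.09375                      83.87097
```

Of 59 annotated query loci, 16 form conserved families (members from at
least four species spanning both lineages), ~98% of planted surviving
homologs within 42 Myr of the focal species are recovered with no false
promotions, and ~96% of the loss/decay calls match the planted states.
Downstream summaries come straight off the result tables:

```r
depth_stratified_proportions(pipe$features, "stress_responsive")
#>   depth_age  n n_flag prop_pct p_value
#> 1         0 20      1      5.0      NA
#> 2        13  8      0      0.0    1.00
#> ...
#> 5        42  9      3     33.3   0.076
#> 7        65  4      2     50.0   0.061

expression_depth_correlation(pipe$features)
#> expression ~ conservation depth: r = 0.743  slope = 0.0116
#> log10-FPKM/Myr, p = 1.58e-11  (n = 59)
```

The stress-responsive fraction climbs with conservation depth and
expression rises ~0.012 log10-FPKM per Myr of depth — the planted
covariate gradients, recovered through the full pipeline. Further
summaries:

```r
# duplication events binned along the backbone
pipe$dup_summary$per_node

# which species lose loci at indistinguishable rates?
group_species(pipe$loss_decay, metric = "lost")$groups

# tidy/glance on the expression fit
fit <- expression_depth_correlation(pipe$features)
tidy(fit); glance(fit)
```

`plot_depth_proportions()`, `plot_species_groups()`,
`plot_duplication_timing()` and `autoplot()` on the expression fit give
the corresponding figures. See `vignettes/lincrna-evolution.Rmd` for the
model, its assumptions, and every tunable parameter.

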