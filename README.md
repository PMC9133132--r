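# polpause

Quantification of RNA polymerase II pausing at transcript ends from
PRO-seq data, with companion tools for nuclear-body enrichment and
colocalization analysis.

## The problem

PRO-seq (precision nuclear run-on sequencing) maps the 3′ end of nascent
RNA — the active position of the engaged polymerase — at single-nucleotide
resolution. At replication-dependent histone (RDH) genes, whose
non-polyadenylated mRNAs end in a conserved stem-loop, Pol II pauses
immediately upstream of the transcript end site (TES) before termination,
and perturbing the factors behind that pause produces transcriptional
read-through past the TES. `polpause` implements the quantification layer
for this biology:

- **TPP index** (TES-proximal pausing): signal density in a window ending
  at the TES over gene-body density,

  `TPP = (TESr / |TESr|) / ((GB + c) / |GB|)`

  where TESr is the TES-proximal window (default 100 nt, ending at and
  including the TES), GB the gene body between the two pause windows, and
  `c` a denominator pseudocount (default 1).
- **PPP index** (promoter-proximal pausing): the same form with the
  TSS-proximal window (default 150 nt).
- **Read-through ratio**: signal in TES..TES+200 over signal in
  TSS..TSS+200 (a gene-body denominator is selectable), summarized over
  genes whose spike-normalized TSS-proximal signal exceeds 10.
- **Normalization**: exogenous (Drosophila-like) spike-in coverage scaling
  for cross-sample comparison, or rRNA-read-million scaling for samples in
  which Pol II is inhibited (α-amanitin) and spike scaling is confounded.
- **Condition comparisons**: per-gene-class paired two-sided Wilcoxon
  signed-rank tests, exact (full sign-flip enumeration) up to n = 15
  informative pairs.
- **Meta-gene profiles** anchored at TSS or TES, orientation-flipped for
  minus-strand genes.
- **Per-gene IP/input enrichment** (CPM-normalized ratio and difference)
  and fixed-window locus signal, with the two human histone-cluster
  windows as named presets.
- **Particle colocalization**: fixed-threshold particle detection
  (8-connected, intensity-weighted centroids), mask-overlap association
  with per-anchor occupancy, centroid distances in µm, and anchor-centred
  averaged images.

Every stage is driven by a ground-truthed synthetic-data generator
(`simulate_genome()`, `simulate_proseq()`, `simulate_images()`), so the
whole pipeline is testable at desk scale without raw sequencing or
microscopy data.

## Worked example

Simulate a genome with two RDH-like gene clusters, run the wild-type and
3′-pause-deficient presets through the pipeline, and compare the classes:

```r
library(polpause)

genome <- simulate_genome(seed = 42)
genome
#> sim_genome: 4 contigs, 71 genes (seed 42)

wt  <- run_proseq_pipeline(genome, condition = "WT",
                           reads_per_gene = 2000, seed = 42)
class_summary(wt$table, "tpp_index")
#>       gene_class  n        q1    median        q3
#> 1 protein_coding 20 1.0978577 1.5541103 1.8157271
#> 2            RDH 30 2.8053021 3.5236662 4.3496903
#> 3         snoRNA 10 0.2634850 0.3232817 0.3540986
#> 4          snRNA 10 0.7050773 1.0769312 1.5394909

mut <- run_proseq_pipeline(genome, condition = "EAF1_mut",
                           reads_per_gene = 2000, seed = 43)
compare_classes(wt$table, mut$table, "tpp_index",
                classes = c("RDH", "snRNA"))
#>   gene_class n_pairs median_a   median_b statistic      p_value
#> 1        RDH      30 3.523666 0.08655126       465 1.825371e-06
#> 2      snRNA      10 1.076931 1.07347938        33 6.250000e-01
```

RDH genes carry the strongest TES-proximal pausing in the wild type
(median TPP 3.5 versus ~1 for protein-coding genes: TES-proximal signal
density 3.5-fold the gene-body density). In the pause-deficient preset the
RDH median collapses ~40-fold (paired signed-rank p ≈ 2e-6) while snRNA
genes are untouched (p = 0.62) — the class-specific signature the pipeline
is built to measure.

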