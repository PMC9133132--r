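---
title: "Methods: quantifying Pol II pausing at transcript ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Pol II pausing at transcript ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polpause)
```

## Scope and model

`polpause` quantifies where engaged RNA polymerase II sits along genes
from PRO-seq data. PRO-seq reads report the 3′ end of the nascent RNA, so
a single base per read — the 3′-most aligned base in read orientation —
carries all positional information. The package's core object is therefore
a strand-specific, single-nucleotide 3′-end pileup (`signal_track`), and
every downstream statistic is a window sum over that track.

The biological signal of interest is polymerase pausing immediately
upstream of the transcript end site (TES) of replication-dependent histone
(RDH) genes, where the mRNA stem-loop is transcribed, and the
transcriptional read-through past the TES that appears when 3′-end
processing or termination fails. Three per-gene statistics capture this:

* **TPP index** — TES-proximal signal density over gene-body density:
  `(TESr/|TESr|) / ((GB + c)/|GB|)`. Densities, not raw sums, so windows
  of unequal length are comparable; the pseudocount `c` applies to the
  gene-body count only, so a pause over an empty gene body gives a large
  but finite index.
* **PPP index** — the same ratio with the TSS-proximal window, the
  classical promoter-proximal pausing index.
* **Read-through ratio** — signal in TES..TES+200 over signal in
  TSS..TSS+200. A gene-body denominator (`mode = "genebody"`) is provided
  as an alternative; the TSS-window form is the default because both
  windows have the same length and respond identically to initiation-rate
  changes.

## Coordinate conventions and windows

All internal coordinates are 0-based half-open, as in BED arithmetic. The
TSS is the first transcribed base and the TES the *final transcribed
base, inclusive* — this makes "TES to TES + 200 bp" unambiguous: the
read-through window starts one base past the TES. Transcripts sharing an
identical TSS or TES (on the same contig and strand) are collapsed
transitively into a single unit spanning the union, because their 3′ and
5′ windows would otherwise double-count the same pileup; the merged unit
keeps the highest-priority class among its members (RDH first), so a
histone gene overlapped by a host transcript is still analyzed as RDH.

Window defaults, all orientation-aware and configurable in
`define_regions()`:

| window  | default | rationale |
|---------|---------|-----------|
| TSSr    | 150 nt from the TSS | covers typical promoter-proximal pause positions (~30–60 nt) with margin |
| TESr    | 100 nt ending at the TES | the stem-loop pause sits a few tens of nt upstream of the TES; 100 nt contains it with margin |
| GB      | between TSSr and TESr | excludes both pause windows so a pause peak cannot inflate its own denominator |
| tss200 / rt | 200 nt from TSS / from TES+1 | the read-through ratio's printed window length |

The exact TESr/TSSr sizes behind published pausing-index figures are
rarely printed; these defaults are this package's own choice, and both
pause windows are parameters precisely because of that. Genes shorter
than 150 nt, or whose gene body would fall under 50 nt, are flagged
ineligible rather than silently shrunk — a shrunken gene body changes the
index's meaning. Windows crossing contig edges are clipped and flagged,
not fatal, because windows near edges are routine on short synthetic
contigs and at chromosome ends.

## Normalization

Two schemes are implemented, matching the two experimental designs they
serve:

* **Spike-in coverage** (`spike_normalization_factor()`): coverage is
  total aligned bases on the spike contigs divided by the spike genome
  length, and the factor is `reference_coverage / coverage`. Aligned-base
  totals rather than read counts are used because coverage is the quantity
  that is depth- and read-length-honest. Spike coverage is computed from
  all accepted alignments (not 3′-end-collapsed ones); the two choices
  differ only by a read-length constant that cancels across samples.
* **rRNA million** (`rrna_normalization_factor()`): `1e6 / (reads whose
  3′ end falls in the rRNA interval)`. When Pol II is inhibited with
  α-amanitin, both library size and spike share collapse with the Pol II
  signal itself; Pol I transcription does not, so rRNA-mapped reads are
  the stable denominator. The default interval is the 45S rDNA scaffold
  window chrUn_GL000220v1:105424–118780 (GRCh38).

Tracks refuse double scaling: normalization is applied once, and the
units travel with the track. The three pausing statistics are ratios and
therefore invariant to any global rescaling (at pseudocount 0); only the
expression filter — spike-normalized TSS-proximal signal strictly greater
than 10 — depends on the scale, which is exactly why it is defined on the
normalized track. The "10-fold signal" phrasing common in figure legends
leaves the referent implicit; this package pins it to the tss200 window
sum on the spike-normalized track, exposed as `filter_threshold`.

## Paired comparisons

Class-wise condition comparisons use the two-sided Wilcoxon signed-rank
test on genes paired by id. The implementation is in-package because its
behavior is pinned: zero differences are dropped before ranking (the
signed-rank convention), the null is enumerated exhaustively over all
`2^n` sign assignments for n ≤ 15 informative pairs (this handles ties in
|d| exactly), and above that a normal approximation with continuity
correction and tie-corrected variance `sum(r²)/4` is used — numerically
identical to `wilcox.test(..., exact = FALSE, correct = TRUE)`, which the
test suite uses as an independent cross-check alongside a brute-force
enumeration oracle. All differences zero yields p = 1 with a warning
rather than an error, since it is a legitimate (if uninformative)
outcome. No multiple-testing correction is applied across classes:
per-class p-values are reported as such.

## Meta-gene profiles

`anchor_matrix()` stores minus-strand rows already flipped, so offset +x
always means downstream in transcript orientation, and bins (default
10 nt over ±500 nt) partition the window exactly. Two averaging modes are
provided because neither is canonical: plain column means weight genes by
expression; `row_sum` normalization weights genes equally (rows with zero
total are dropped and counted). Windows beyond contig edges contribute
zeros rather than NA so that profile averages stay comparable across
genes.

## Enrichment and locus windows

IP-style tracks are CPM-normalized and compared per gene as both
`(IP + 1)/(input + 1)` and `IP − input`; which is more readable depends on
the track's dynamic range, so both are always emitted. The pseudocount of
1 CPM is a floor for unobserved genes, configurable. Locus-level signal
(`window_signal()`) is a strand-agnostic sum over fixed windows; the two
human histone-cluster windows ship as named presets
(`histone_locus_preset()`).

## Image quantification

Particles are 8-connected components above a fixed intensity threshold
with a minimum area — the particle-analyzer convention, where the
threshold is an explicit input because a "clearly recognizable in the
control" threshold is inherently a per-experiment judgement. Labeling is
implemented as vectorized minimum-label propagation and is verified
against a per-pixel flood-fill oracle in the tests. Centroids are
intensity-weighted, in 0-based pixel coordinates.

Association between anchor and partner channels is mask overlap
(≥ 1 px by default): it matches the occupied-area reading of
colocalization and is threshold-consistent with the detection step. A
centroid-distance alternative (default radius 0.5 µm) is provided for
point-like loci such as DNA-FISH foci, where masks are beads rather than
bodies. Per-anchor occupancy is the fraction of anchor pixels covered by
any partner; association frequencies are reported symmetrically for both
channels. Anchor-centred averaging crops a (2h+1)² window at each rounded
anchor centroid, skipping (and counting) anchors too close to the frame
edge, and emits the horizontal centre line profile per channel. Nuclei
segmentation is out of scope: inputs are assumed pre-masked to nuclear
regions.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
simulated study conditions:

* **Genome**: two 120-kb host contigs each carrying a cluster of RDH-like
  genes (30 by default, 450–700 nt, mirroring compact histone genes in
  two clusters) plus dispersed snRNA/snoRNA (350–600 nt) and
  protein-coding genes (1–3 kb); a 50-kb gene-free spike contig; a 20-kb
  rRNA contig with one heavily transcribed Pol-I-like gene whose body
  doubles as the rRNA normalization interval.
* **Reads**: each 3′ end is drawn per gene from a four-component mixture —
  uniform over the TSS-proximal window (w5), uniform over the gene body
  (wgb), a discretized Gaussian centred 35 nt upstream of the TES with
  width 10 nt (w3; the stem-loop pause position), and TES + geometric tail
  with mean 50 nt (rho; read-through). Read bodies are uniform 25–50 nt
  ending at the 3′ end, as after base hydrolysis; the length distribution
  is immaterial to 3′-end statistics. Spike reads are 10% of the library,
  the standard spike-in cell proportion.
* **Presets**: wild type (RDH w3 = 0.40, snRNA 0.25, snoRNA 0.10,
  protein-coding 0.05; rho = 0.05 everywhere); a 3′-pause-deficient
  mutant (RDH w3 ×0.05, rho ×2); NELF depletion (RDH w3 ×0.5, snRNA w3
  ×0.85); and Pol II inhibition (all non-rRNA expected counts ×0.1, rRNA
  untouched). Weight changes re-enter the gene-body component so weights
  always sum to 1.
* **Images**: Gaussian blobs (σ = 2 px, peak 100 counts over background
  2) with Poisson noise; a fraction f of anchors get a partner displaced
  by a vector of length uniform in [0, 2σ], the rest of the partners are
  kept ≥ 10σ from any anchor, so ground-truth association is unambiguous
  at the detection threshold.

All randomness flows from one master seed through named substreams, so
identical seed and configuration give identical outputs, including
written files.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: mappability artifacts and multi-mapping, base
composition and sequence-dependent run-on biases, overlapping or nested
transcription units, antisense transcription, nuclear background
structure in images, chromatic shift, and out-of-focus light. Recovery
results on the simulator validate the estimators' arithmetic and
invariances, not robustness to those artifacts.

## Problem sizes and numerical choices

The shipped checks run at sizes chosen to make sampling error small
relative to the tested effects while staying desk-scale: 20,000 reads per
gene for index recovery (median TPP within ±15% of truth at ratios 5, 20
and 100) and for the 30-gene condition comparisons; 5,000 reads per gene
at n = 40 for the depletion contrast; Poisson per-gene depths over 10
seeds for the Pol II-inhibition stability check; 10 frames × 300 anchors
for association recovery against the exact 99% binomial interval.
`scripts/acceptance.R` recomputes all of these from scratch at run time.

Remaining numerical conventions: window counting is strand-matched to the
gene; genes with a zero read-through denominator are dropped from ratio
summaries rather than given infinities; boxplot-style class summaries use
only eligible, filter-passing genes; the expression filter is a strict
inequality; and ineligible genes carry NA indices plus a reason string
rather than propagating NaN.

## Known limitations

Exon structure is ignored (transcription units are intervals), so the
gene-body density of heavily spliced genes mixes exonic and intronic
run-on signal. Genes whose windows overlap a neighbour's — common inside
dense histone clusters — are neither clipped nor excluded by default;
their counts genuinely overlap, and callers who want exclusivity must
filter on the exported windows. The SAM/BAM reader uses the aligned span,
so 3′ soft-clipped bases (e.g. untrimmed adapter) shift the recorded 3′
end. The image module is 2D: axial structure in the particle association
is projected away.
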