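---
title: "Methods: chromatin loop and regulatory element analysis with regloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin loop and regulatory element analysis with regloops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`regloops` implements the downstream portion of a plant ChIA-PET study:
everything after read alignment, peak calling and FPKM quantification. The
inputs are gene models (GFF3), ChIP peak calls with intensity (BED), heavy-
and light-digest MNase peaks (BED), per-cytosine bisulfite methylation
calls, paired-end tags (BEDPE), a genes x tissues FPKM matrix, and
eQTL/GWAS association tables. The outputs are annotated regulatory
elements, called chromatin loops, their PPI/PDI classification, a looped
gene-pair co-expression test against distance-matched permutation nulls,
and eQTL/GWAS-loop enrichment tests against simulated-loop and
random-region nulls.

All coordinates inside the package are 0-based half-open (BED-like); GFF3
conversion on read/write is the only coordinate shift in the code base.
Overlap always means at least one shared base on half-open intervals,
unless a larger minimum is requested explicitly.

# Element annotation

**Promoter-proximal regions** span 2 kb upstream to 1.5 kb downstream of
the transcription start site, oriented by strand and clipped at chromosome
ends. On the minus strand the window is mirrored as
`[tss - 1500, tss + 2000)`; with half-open intervals the TSS base itself
necessarily falls on one side (downstream for `+` genes, upstream for `-`
genes), an off-by-one that is irrelevant at the 3.5-kb window scale but is
fixed here for determinism.

**LUMRs** (low/unmethylated methylation regions) are called on a fixed
200-bp genome tiling. Per bin and context, the methylation level is the
coverage-weighted mean `sum(n_meth) / sum(n_total)` over sites with depth
of at least 3; a bin passes when CG < 0.2, CHG < 0.1 and CHH < 0.1, all
strict. A context with no covered site in a bin passes by default: absence
of evidence for methylation is not treated as methylation, and the CG/CHG
thresholds are the discriminating ones in practice. Adjacent passing bins
merge into one region. The thresholds, bin size and coverage floor are all
arguments.

**Distal elements** start from heavy-digest MNase peaks. "Subtracting"
the light digest is implemented as set subtraction — any heavy peak
sharing at least `min_overlap` (default 1) bp with a light peak is dropped
— rather than signal-level subtraction, because the operation is defined
on peak sets. Remaining candidates are removed if they touch a gene body,
a gene body extended by 2 kb on both sides (strand-symmetric; the
flank is a parameter), or an H3K4me3 peak, and are kept only when they
overlap at least one LUMR. The four filters are pure intersections, so
their order cannot change the result; a test asserts this.

**TSS signal profiles** extract per-gene vectors of 50-bp binned coverage
over +/- 3 kb around the TSS, flipping minus-strand genes so upstream is
always left. Bins beyond the chromosome edge are `NA`, not zero — a zero
would fabricate signal absence. K-means with `k = 15` (package default),
10 restarts and a fixed seed clusters the concatenated per-mark profiles
into chromatin states; states are relabeled by decreasing size so label 1
is always the largest, making labels comparable across runs.

# PET processing and loop calling

PETs are categorized by the genomic span between tag midpoints:
different chromosomes are interchromosomal; spans below 8 kb are
self-ligation products; the rest are inter-ligation PETs. The 8-kb cut is
not dictated by the data model — it is the conventional ChIA-PET
self-ligation span — and is exposed as `self_span_threshold`.

Loops are called from inter-ligation PETs only. Tags are extended by
500 bp on each side and overlapping extensions merged into anchor regions
(reproducing anchors of roughly 1 kb); PETs are grouped by their anchor
pair; a pair becomes a loop when supported by at least 3 PETs with at
least one anchor overlapping a ChIP peak of the library's mark. Peak
support is recorded as `both` or `one`. The extension-and-merge anchor
construction is a deliberate, stated approximation of full ChIA-PET
clustering tools; its parameters are arguments.

Contact matrices count PET tag pairs per bin pair at a configurable
resolution (1 Mb / 50 kb / 5 kb conventionally). Distance normalization is
observed/expected with the expected value equal to the mean observed count
over all bin pairs at the same separation; distances with no mass stay 0.

# Interaction classes

A loop is a **PPI** when its anchors overlap promoter-proximal regions of
at least one cross-anchor pair of *different* genes (two anchors inside
the same single promoter do not qualify), and a **PDI** when one anchor
overlaps a distal element and the other a promoter region. A loop
qualifying as both is labeled PPI; this precedence keeps the partition
disjoint, and `dual_labels = TRUE` reports the joint label instead. Genes
partition into **anchor** (promoter overlaps a loop anchor), **basal**
(H3K4me3 or RNAPII peak but no loop) and **other**. Distal elements in
PDIs are **single** or **multiple** by the number of distinct target
genes — genes, not loops, are counted, so one element reaching one gene
through two loops is still single.

The PPI network has genes as nodes and unique PPI pairs as edges weighted
by the maximum supporting PET count; subnetwork ranking keeps edges with
PET count strictly greater than 4 and orders components by size. The
anchor versus non-anchor peak intensity contrast uses the two-sided
Wilcoxon rank-sum test.

# Co-expression against distance-matched nulls

Expression breadth counts tissues with FPKM strictly above 1; CV is the
sample (n-1) standard deviation over the mean, with a flag for zero-mean
genes and a switch for the population SD. Ranking ascending by CV (gene-id
tie-break), the lowest-CV genes are reported as housekeeping and the
highest-CV as tissue-specific: stable expression across tissues is the
defining property of housekeeping genes, which fixes the direction of the
ranking.

The co-expression test compares Pearson correlations of looped gene pairs
(TSS-to-TSS distance defines pair distance) with two random controls:
mode A, uniform same-chromosome pairs; mode B, pairs matched on the
observed log-distance histogram (natural log, 20 equal-width bins over the
observed range) and restricted to genes carrying an H3K4me3 or RNAPII peak
(either mark — the mark identity is not matched per pair). Candidates
equal to an observed pair are excluded before sampling, so every replicate
reproduces the observed per-bin counts exactly; an empty bin raises an
error naming the bin. Correlations are computed on `log1p(FPKM)` by
default: FPKM is lognormal-scaled and the planted effect lives on the log
scale; a switch restores raw-scale correlation. Inference reports a
two-sample t-test of observed versus pooled null correlations plus an
empirical p from per-replicate null means with the add-one estimator
`(1 + #{null >= observed}) / (reps + 1)`, which cannot return zero.

# eQTL and GWAS integration

SNPs annotate to exactly one of promoter / distal element / gene body /
intergenic, with that precedence. An eQTL-etrait pair is *looped* when one
anchor of a loop overlaps the 4-kb window centered on the top SNP
(SNP +/- 2 kb, half-open) and the other anchor overlaps the etrait gene's
promoter. Genes then classify as eQTL genes (associated, not looped),
looped genes (associated and looped), eQTL-interacting genes (not
associated, but promoter connected to an eQTL window by a loop), plus a
random control sampled from unclassified genes matched on log distance to
the nearest eQTL SNP (falling back to the whole pool in empty bins, which
small genomes make common).

The simulated-loop null re-places each loop uniformly on its own
chromosome, preserving span and both anchor widths exactly (the whole
footprint is placed, so no rejection step is needed except the hard error
when a loop exceeds its chromosome); anchor-peak support is *not*
preserved, which is noted as a limitation. The GWAS test counts distal
elements overlapping 200-kb windows centered on SNPs (SNP +/- 100 kb) and
compares PDI-interacting elements against non-interacting elements and
against chromosome- and length-matched random regions. Both tests report
the add-one empirical p over the null counts and a t-test of the null
counts against the observed count.

Category correlation contrasts (eQTL:eQTL, eQTL:Loop,
eQTL_interacting:Loop, Random:Loop, Random:eQTL_interacting) pair genes of
the two categories within a configurable TSS distance (default 1 Mb) when
gene positions are supplied. The restriction matters: the scientific claim
is about genes at the same locus (an interacting gene and the looped gene
of the same eQTL), and an unrestricted cross product of categories dilutes
any locus-level signal toward zero by construction.

# The synthetic-data generator

`generate_bundle()` emits every input above with planted ground truth and
is byte-reproducible given `(config, seed)`. What it emulates, and how:

* **Genes** are placed without overlap (stick-breaking over the free
  slack, minimum gap 6 kb) so promoter and flank exclusion rules are
  unambiguous; strands are random.
* **Loops** (default 50; spans uniform in 10–100 kb, matching the span
  range reported for promoter-proximal loops) split into PPI pairs
  (anchors ~0.8–1.2 kb at the two TSSs), PDIs (element anchor to promoter
  anchor; a configurable fraction of elements carries two PDIs, making
  multi-target elements), and "other" loops in clear intergenic space.
  Every loop gene carries an H3K4me3 peak so called loops pass the
  peak-support filter; one anchor of each "other" loop gets a decoy peak.
* **PETs**: each planted loop expands to 3–8 tags jittered within its
  anchors; 1000 noise PETs have uniform positions and log-uniform spans
  (a quarter below the self-ligation cut, to exercise categorization).
* **Methylation**: sites every 40 bp with a deterministic CG/CHG/CHH
  cycle (guaranteeing every 200-bp bin observes every context at desk
  scale — random context placement would create false LUMR bins through
  coverage gaps), background means CG 0.85 / CHG 0.70 / CHH 0.05
  (maize-like heavily methylated intergenic space; CHH is genuinely below
  its threshold genome-wide, so CG/CHG carry the discrimination), planted
  blocks at CG 0.05 / CHG 0.02 / CHH 0.01 aligned to the 200-bp calling
  grid. Binomial read sampling occasionally pushes one bin of a block over
  a threshold and splits it; recovery metrics are overlap-based, so this
  is visible (a few extra called regions) but harmless.
* **Expression** (79 tissues): `FPKM = exp(mu_g + x)` with gene baselines
  `mu_g ~ N(log 10, 1)`; each looped pair shares a latent tissue factor,
  `x = sqrt(rho) z_pair + sqrt(1 - rho) noise` with `rho = 0.6`, so the
  planted Pearson correlation is `rho` on the log scale (recovered at
  about 0.59 after the lognormal transform and `log1p` readback).
  Multi-target elements plant the same sharing between their two genes,
  which is what the category correlation contrast detects.
* **eQTLs** (100, half loop-linked): a linked record puts its SNP inside
  the distal element of a PDI whose other anchor is its etrait gene's
  promoter; partner genes of multi-target elements are never used as
  etraits, so the eQTL-interacting category has planted members. Unlinked
  records place SNPs in the bodies of loop-free genes with loop-free
  etraits, far from all anchors, so no accidental links arise.
* **GWAS SNPs** (20; half linked within 25 kb of distinct interacting
  elements). The counts are deliberately sparse: windows of 200 kb around
  many SNPs would tile a 10-Mb toy genome completely (window coverage near
  1 makes every element a hit and no contrast measurable at any effect
  size), whereas real QTL sets cover a small fraction of a 2.3-Gb genome.
  Twenty SNPs keep window coverage near one third.

What the generator does **not** emulate: read-level noise (alignment,
duplicates, bisulfite conversion), realistic karyotype and repeat content,
promoter hypomethylation (planted LUMRs are intergenic only, so the
planted set is exactly the callable set), anchor-width heterogeneity
beyond ~1 kb, trans-eQTLs with interchromosomal support, and expression
matrices with dropout or batch structure. Passing recovery tests on these
bundles therefore demonstrates correctness of the operations and filters,
not robustness to upstream noise in real libraries.

# Numerical choices and validation sizes

Tie-breaks and degenerate inputs: CV ranking breaks ties by gene id;
k-means states relabel by size; empty peak lists yield empty element sets
(not errors); an unlabelable loop is `other`; identical intensity groups
give a Wilcoxon p near 1. Empirical p-values always use the add-one
estimator. The distance-bin index clamps boundary values into `[1, 20]` so
the extreme observed pairs stay in the outer bins.

Validation uses these problem sizes, chosen to give stable statistics at
interactive runtimes: the reference recovery bundle is 1 chromosome x
10 Mb, 300 genes, 50 loops, 20 LUMRs, 1000 noise PETs; the co-expression
effect check uses 3 chromosomes, 900 genes and at least 200 planted pairs
with 79 tissues; null calibration runs 200 simulated datasets per test
with 200 permutation/simulation replicates each, 15-tissue expression
matrices, 30 loops/40 eQTLs, and 20 elements/15 SNPs. Oracle-equivalence
suites run 100 random instances per operation against brute-force
reimplementations (per-bin methylation scan, direct breadth/CV loops,
incidence-counted degrees, membership-checked SNP annotation).

# Known limitations

The anchor construction approximates, not reproduces, published ChIA-PET
tool clustering; absolute loop counts from real libraries are not
comparable. The simulated-loop null does not preserve anchor-peak
support. LUMR calling reports a single threshold set; a stricter
"unmethylated" subclass would need a second configuration. Trans-eQTL
loop support is limited to same-chromosome records unless
interchromosomal loops are supplied. The housekeeping/tissue-specific
direction (lowest CV = housekeeping) is a documented convention choice.
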