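# regloops

Downstream analysis of ChIA-PET chromatin interaction maps in plant
genomes, built for the maize promoter-interactome setting: annotating
regulatory elements from epigenomic tracks, calling chromatin loops from
paired-end tags, classifying promoter-promoter (PPI) and promoter-distal
(PDI) interactions, testing whether looped gene pairs are co-expressed
against distance-matched permutation nulls, and linking eQTL/GWAS variants
to their target genes through loops with simulated-loop and random-region
null models. A seed-reproducible synthetic-data generator with a planted
ground-truth manifest supports end-to-end validation of every stage.

It is aimed at regulatory genomicists who already have aligned, peak-called
data (genes as GFF3; ChIP and MNase peaks as BED; per-cytosine methylation,
FPKM and association tables as TSV; PETs as BEDPE) and want the analysis
layer between those files and the biology.

## The core operations

* **Promoter-proximal regions**: TSS − 2 kb to TSS + 1.5 kb, strand-aware.
* **LUMRs** (low/unmethylated methylation regions): 200-bp bins whose
  coverage-weighted methylation satisfies CG < 0.2, CHG < 0.1, CHH < 0.1
  (strict), merged when adjacent.
* **Distal elements**: heavy-digest MNase peaks minus light-digest peaks,
  excluding anything within 2 kb of a gene or touching H3K4me3, kept only
  when hypomethylation (a LUMR) supports them.
* **Loop calling**: PETs categorized by span (self-ligation < 8 kb,
  inter-ligation, interchromosomal); tags extended ±500 bp and merged into
  ~1-kb anchors; a loop requires PET count ≥ 3 and ≥ 1 anchor on a ChIP
  peak. Contact matrices are distance-normalized as observed/expected,
  where expected is the mean count at each bin separation.
* **Co-expression**: Pearson correlation of looped gene pairs versus
  (A) random same-chromosome pairs and (B) pairs matched on the observed
  log-distance histogram (20 bins) among peak-marked genes; two-sample
  t-test plus an add-one empirical p over replicate null means,
  `p = (1 + #{null ≥ obs}) / (reps + 1)`.
* **eQTL/GWAS integration**: an eQTL-etrait pair is "looped" when a 4-kb
  window on the top SNP hits one anchor and the etrait promoter the other;
  enrichment is tested against loops re-placed uniformly per chromosome
  with spans and anchor widths preserved. Distal elements are tested for
  GWAS proximity in 200-kb SNP windows against length-matched random
  regions.

## Worked example

The `analysis/` scripts run the whole workflow on a generated bundle:

```sh
Rscript analysis/01_simulate.R      # synthetic inputs + ground truth
Rscript analysis/02_elements.R      # promoters, LUMRs, distal elements
Rscript analysis/03_loops.R         # PET categories, loops, contact map
Rscript analysis/04_classify.R      # PPI/PDI, gene/element categories, network
Rscript analysis/05_coexpression.R  # breadth/CV, matched-null co-expression
Rscript analysis/06_qtl.R           # SNP annotation, eQTL/GWAS enrichment
```

On the default bundle (one 10-Mb chromosome, 300 genes, 50 planted loops,
20 hypomethylated blocks, 1000 noise PETs, 79 tissues) this prints, among
other things:

```
called 50 loops (100% intra-chromosomal)
planted-loop recovery: precision 1.000, recall 1.000
loop labels:
other   PDI   PPI
   10    15    25
distal elements in PDIs: 13 (11 single + 2 multiple)
mean r: observed 0.580 | null A -0.002 | null B -0.013
observed - null B difference: 0.593 (t-test p 6.32e-22, empirical p 0.00498)
looped eQTL-etrait pairs: 50 / 100
eQTL-loop enrichment: observed 50, null mean 0.12, empirical p 0.000999
GWAS 200-kb windows: hit rate interacting 0.85, non-interacting 0.40,
random 0.31; empirical p 0.000999
```

Reading this: all 50 planted loops survive the PET-count and peak-support
filters with no false calls; the 25 planted promoter-promoter pairs show
the planted co-expression effect (difference ≈ 0.59 against the
distance-matched null, consistent with the generated ρ = 0.6); and the 50
eQTLs planted inside looped distal elements are all recovered, far above
the ~0.1 pairs expected when the same loops are placed at random.

Equivalent calls in R: `generate_bundle()`, `run_pipeline()` and
`evaluate_against_manifest()` chain the same stages programmatically.

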