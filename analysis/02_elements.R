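#!/usr/bin/env Rscript

## Annotate regulatory elements on the bundle written by 01_simulate.R:
## promoter-proximal regions (TSS -2 kb / +1.5 kb), low/unmethylated
## regions (LUMRs; CG < 0.2, CHG < 0.1, CHH < 0.1 in 200-bp bins), and
## candidate distal elements (heavy-MNase peaks minus light-MNase peaks,
## away from genes +/- 2 kb and H3K4me3, overlapping a LUMR). Also profiles
## H3K4me3 signal around TSSs and clusters genes into chromatin states.

suppressMessages({library(regloops); library(data.table)})

b <- read_bundle("results/bundle")
dir.create("results/elements", recursive = TRUE, showWarnings = FALSE)

promoters <- call_promoter_regions(b$genes, chrom_lengths = b$chrom_lengths)
lumrs <- call_lumrs(b$methylation)
elements <- call_distal_elements(b$peaks$MNase_heavy, b$peaks$MNase_light,
                                 b$genes, b$peaks$H3K4me3, lumrs)
fwrite(promoters, "results/elements/promoters.tsv", sep = "\t")
fwrite(lumrs, "results/elements/lumrs.tsv", sep = "\t")
fwrite(elements, "results/elements/distal_elements.tsv", sep = "\t")

## 50-bp coverage track from H3K4me3 peak intervals, then TSS states
bin <- 50L
track <- lapply(names(b$chrom_lengths), function(ch) {
  v <- numeric(ceiling(b$chrom_lengths[[ch]] / bin))
  pk <- b$peaks$H3K4me3[chrom == ch]
  for (i in seq_len(nrow(pk))) {
    lo <- pk$start[i] %/% bin + 1L; hi <- (pk$end[i] - 1L) %/% bin + 1L
    v[lo:hi] <- v[lo:hi] + pk$intensity[i]
  }
  v
})
names(track) <- names(b$chrom_lengths)
prof <- signal_profile(b$genes, track, flank = 3000, bin = bin)
states <- cluster_tss_states(list(H3K4me3 = prof), k = 15, seed = 1)
fwrite(data.table(gene_id = names(states), state = states),
       "results/elements/tss_states.tsv", sep = "\t")

cat(sprintf("promoters: %d, LUMRs: %d, distal elements: %d, TSS states: %d\n",
            nrow(promoters), nrow(lumrs), nrow(elements),
            length(unique(states))))
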