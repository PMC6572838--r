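#!/usr/bin/env Rscript

## Generate the reference synthetic input bundle and write it to disk.
##
## The bundle emulates the inputs of a maize ChIA-PET downstream analysis:
## GFF3 gene models, H3K4me3/RNAPII ChIP peaks, heavy/light MNase peaks,
## per-cytosine methylation calls, paired-end tags (planted loops expanded
## to >= 3 supporting PETs each, plus uniform noise), a 79-tissue FPKM
## matrix with a planted co-expression effect for looped gene pairs, and
## eQTL/GWAS tables with loop-linked records. The planted ground truth is
## stored in results/bundle/manifest.json.

suppressMessages(library(regloops))

seed <- 1L
out <- "results/bundle"

cfg <- synth_config(seed = seed)
bundle <- generate_bundle(cfg)
write_bundle(bundle, out)

cat(sprintf("wrote synthetic bundle to %s\n", out))
cat(sprintf("  genes: %d, PETs: %d (%d noise), planted loops: %d\n",
            nrow(bundle$genes), nrow(bundle$pets), cfg$n_noise_pets,
            nrow(bundle$manifest$loops)))
cat(sprintf("  planted LUMRs: %d, distal elements: %d, eQTLs: %d (linked %d)\n",
            nrow(bundle$manifest$lumrs), nrow(bundle$manifest$distal_elements),
            nrow(bundle$eqtls), sum(bundle$manifest$eqtls$linked)))
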