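#!/usr/bin/env Rscript

## Categorize PETs (self-ligation vs inter-ligation vs interchromosomal),
## call loops (PET count >= 3, >= 1 anchor on an H3K4me3 peak), and build a
## distance-normalized (observed/expected) contact matrix.

suppressMessages({library(regloops); library(data.table)})

b <- read_bundle("results/bundle")
dir.create("results/loops", recursive = TRUE, showWarnings = FALSE)

pets <- categorize_pets(b$pets, self_span_threshold = 8000)
cat("PET categories:\n"); print(table(pets$category))

loops <- call_loops(pets[category == "inter_ligation"], b$peaks$H3K4me3,
                    min_pet_count = 3, anchor_extension = 500)
write_bedpe(loops, "results/loops/loops.bedpe")
loc <- classify_loop_locality(loops)
cat(sprintf("called %d loops (%.0f%% intra-chromosomal)\n",
            nrow(loops), 100 * loc[locality == "intra"]$fraction))

supp <- loop_support_summary(loops)
cat(sprintf("peak support both/one: %s / %s (total %d)\n",
            supp$counts["both"], supp$counts["one"], supp$total))

cm <- distance_normalize(contact_matrix(pets[category != "interchromosomal"],
                                        "chr1", b$chrom_lengths[["chr1"]],
                                        resolution = 50000))
fwrite(as.data.table(cm$normalized), "results/loops/contact_oe_50kb.tsv",
       sep = "\t", col.names = FALSE)

## recovery against the planted truth
manifest <- b$manifest
m <- regloops:::match_loops(loops, manifest$loops)
cat(sprintf("planted-loop recovery: precision %.3f, recall %.3f\n",
            length(unique(m$called_idx)) / nrow(loops),
            length(unique(m$planted_idx)) / nrow(manifest$loops)))
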