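#!/usr/bin/env Rscript

## Classify loops into PPI (promoter-promoter) / PDI (promoter-distal) /
## other, partition genes into anchor / basal / other, split distal
## elements into single- vs multi-target, compare anchor vs non-anchor peak
## intensity, and rank the top PPI subnetworks (edges with PET count > 4).

suppressMessages({library(regloops); library(data.table)})

b <- read_bundle("results/bundle")
dir.create("results/classify", recursive = TRUE, showWarnings = FALSE)

promoters <- fread("results/elements/promoters.tsv")
elements <- fread("results/elements/distal_elements.tsv")
loops <- read_bedpe("results/loops/loops.bedpe")
loops[, `:=`(pet_count = count, loop_id = sprintf("loop_%d", .I))]

lc <- classify_loops(loops, promoters, elements)
fwrite(lc, "results/classify/loop_classes.tsv", sep = "\t")
cat("loop labels:\n"); print(table(lc$label))

gc <- classify_genes(b$genes, promoters, loops,
                     rbind(b$peaks$H3K4me3, b$peaks$RNAPII))
fwrite(gc, "results/classify/gene_categories.tsv", sep = "\t")
cat("gene categories:\n"); print(table(gc$category))

ec <- classify_distal_elements(lc)
fwrite(ec, "results/classify/element_classes.tsv", sep = "\t")
cat(sprintf("distal elements in PDIs: %d (%d single + %d multiple)\n",
            nrow(ec), sum(ec$label == "single"), sum(ec$label == "multiple")))

cmp <- compare_anchor_peak_intensity(rbind(b$peaks$H3K4me3, b$peaks$RNAPII), loops)
cat(sprintf("anchor vs non-anchor peak intensity: Wilcoxon p = %.3g\n", cmp$p_value))
print(cmp$summary)

net <- build_ppi_network(lc, b$expression)
deg <- degree_expression_summary(net)
fwrite(deg, "results/classify/ppi_degrees.tsv", sep = "\t")
top <- top_subnetworks(net, n = 100, min_pet_count = 4)
fwrite(top, "results/classify/top_subnetworks.tsv", sep = "\t")
cat(sprintf("PPI network: %d genes, %d edges; %d subnetworks with PET > 4\n",
            nrow(deg), igraph::ecount(net), nrow(top)))
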