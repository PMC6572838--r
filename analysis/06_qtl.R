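#!/usr/bin/env Rscript

## eQTL/GWAS integration: annotate SNPs, link eQTL-etrait pairs to loops
## through 4-kb SNP windows, classify genes relative to eQTLs, and test
## enrichment against the simulated-loop and random-region null models.

suppressMessages({library(regloops); library(data.table)})

b <- read_bundle("results/bundle")
dir.create("results/qtl", recursive = TRUE, showWarnings = FALSE)

promoters <- fread("results/elements/promoters.tsv")
elements <- fread("results/elements/distal_elements.tsv")
loops <- read_bedpe("results/loops/loops.bedpe")
loops[, `:=`(pet_count = count, loop_id = sprintf("loop_%d", .I))]
lc <- fread("results/classify/loop_classes.tsv")
ec <- fread("results/classify/element_classes.tsv")

ann <- annotate_snps(b$eqtls, promoters, elements, b$genes)
cat("eQTL SNP annotation:\n")
print(round(100 * prop.table(table(ann$category)), 2))
fwrite(ann, "results/qtl/snp_annotation.tsv", sep = "\t")

ov <- eqtl_loop_overlap(b$eqtls, loops, promoters, snp_window = 4000)
fwrite(ov, "results/qtl/eqtl_loop_overlap.tsv", sep = "\t")
cat(sprintf("looped eQTL-etrait pairs: %d / %d\n", sum(ov$looped), nrow(ov)))

calls <- classify_eqtl_genes(ov, loops, promoters, b$genes, seed = 11)
fwrite(calls, "results/qtl/eqtl_gene_categories.tsv", sep = "\t")
print(table(calls$category))

enr <- simulate_loops_null(loops, b$chrom_lengths, b$eqtls, promoters,
                           snp_window = 4000, reps = 1000, seed = 12)
cat(sprintf("eQTL-loop enrichment: observed %d, null mean %.2f, empirical p %.3g\n",
            enr$observed, mean(enr$null_counts), enr$empirical_p))

inter <- elements$element_id %in% ec$element_id
gw <- gwas_element_enrichment(elements, inter, b$gwas_snps, b$chrom_lengths,
                              window = 200000, reps = 1000, seed = 13)
cat(sprintf(paste0("GWAS 200-kb windows: hit rate interacting %.2f, ",
                   "non-interacting %.2f, random %.2f; empirical p %.3g\n"),
            gw$hit_rate_interacting, gw$hit_rate_non_interacting,
            gw$hit_rate_random, gw$empirical_p))

cc <- category_correlation_contrast(calls, b$expression, genes = b$genes,
                                    max_pair_distance = 250e3, seed = 14)
fwrite(data.table(pairing = names(cc$correlations),
                  n_pairs = vapply(cc$correlations, length, integer(1)),
                  mean_r = vapply(cc$correlations, mean, numeric(1))),
       "results/qtl/category_correlations.tsv", sep = "\t")

ev <- data.table(
  test = c("eqtl_loop_enrichment", "gwas_element_enrichment"),
  observed = c(enr$observed, gw$observed),
  null_mean = c(mean(enr$null_counts), mean(gw$null_counts)),
  empirical_p = c(enr$empirical_p, gw$empirical_p)
)
fwrite(ev, "results/qtl/enrichment_summary.tsv", sep = "\t")
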