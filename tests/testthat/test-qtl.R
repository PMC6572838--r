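test_that("SNP annotation follows the precedence and matches hand labels", {
  genes <- mk_genes(tss = c(20000, 80000), strand = "+")
  proms <- call_promoter_regions(genes)
  de <- data.table(element_id = "d1", chrom = "chr1", start = 200000L, end = 200600L)
  ## SNP in promoter that is also inside the gene body -> promoter wins
  snps <- data.table(
    snp_chrom = "chr1",
    snp_pos = c(20500L,    # promoter (and gene body)
                200100L,   # distal element
                81800L,    # gene body beyond promoter downstream edge
                400000L)   # nothing
  )
  ann <- annotate_snps(snps, proms, de, genes)
  expect_equal(ann$category,
               c("promoter_proximal", "distal_element", "gene_body", "intergenic"))
  ## total partition
  expect_false(anyNA(ann$category))
})

test_that("SNP annotation agrees with a brute-force oracle on random inputs", {
  set.seed(31)
  for (trial in 1:100) {
    genes <- mk_genes(tss = sort(sample(seq(20000, 900000, by = 9000), 8)))
    proms <- call_promoter_regions(genes)
    de <- data.table(element_id = sprintf("d%d", 1:3), chrom = "chr1",
                     start = sort(sample(seq(10000, 950000, 1000), 3)))
    de[, end := start + 700L]
    snps <- data.table(snp_chrom = "chr1", snp_pos = sample(1e6, 30))
    ann <- annotate_snps(snps, proms, de, genes)
    expect_equal(ann$category, oracle_snp_categories(snps, proms, de, genes))
  }
})

test_that("eQTL window arithmetic counts anchors inside 4-kb windows only", {
  genes <- mk_genes(tss = 500000, strand = "+")
  proms <- call_promoter_regions(genes)
  loops <- data.table(loop_id = "l1",
                      chromA = "chr1", startA = 100000L, endA = 101000L,
                      chromB = "chr1", startB = 499500L, endB = 500500L,
                      pet_count = 3L)
  mk_eqtl <- function(pos) data.table(snp_chrom = "chr1", snp_pos = pos,
                                      gene_id = "g1", type = "cis")
  ## SNP 1.5 kb left of the anchor edge: window reaches the anchor
  expect_true(eqtl_loop_overlap(mk_eqtl(98500L), loops, proms)$looped)
  ## SNP 2.5 kb away: window falls short
  expect_false(eqtl_loop_overlap(mk_eqtl(97499L), loops, proms)$looped)
})

test_that("planted eQTL-loop links are recovered exactly from the bundle", {
  b <- default_bundle()
  pets <- categorize_pets(b$pets)
  loops <- call_loops(pets[category == "inter_ligation"], b$peaks$H3K4me3)
  proms <- call_promoter_regions(b$genes, chrom_lengths = b$chrom_lengths)
  ov <- eqtl_loop_overlap(b$eqtls, loops, proms)
  expect_equal(ov$looped, b$manifest$eqtls$linked)
})

test_that("eQTL gene categories are disjoint and follow the definitions", {
  b <- default_bundle()
  pets <- categorize_pets(b$pets)
  loops <- call_loops(pets[category == "inter_ligation"], b$peaks$H3K4me3)
  proms <- call_promoter_regions(b$genes, chrom_lengths = b$chrom_lengths)
  ov <- eqtl_loop_overlap(b$eqtls, loops, proms)
  calls <- classify_eqtl_genes(ov, loops, proms, b$genes)
  expect_equal(nrow(calls), nrow(b$genes))
  tab <- table(calls$category)
  expect_true(all(c("eqtl_gene", "looped_gene", "eqtl_interacting_gene") %in% names(tab)))
  ## looped genes are associated; interacting genes are not
  expect_true(all(calls[category == "looped_gene"]$gene_id %in% b$eqtls$gene_id))
  expect_false(any(calls[category == "eqtl_interacting_gene"]$gene_id %in% b$eqtls$gene_id))
  ## the two planted genes of each multi-target element land in the expected
  ## categories: the etrait is looped, its partner interacting
  linked <- b$manifest$eqtls[linked == TRUE]
  expect_true(all(linked$gene_id %in% calls[category == "looped_gene"]$gene_id))
})

test_that("simulated-loop null preserves spans and anchor widths", {
  b <- default_bundle()
  pets <- categorize_pets(b$pets)
  loops <- call_loops(pets[category == "inter_ligation"], b$peaks$H3K4me3)
  set.seed(1)
  shuf <- regloops:::shuffle_loops(loops, b$chrom_lengths)
  expect_equal(shuf$endA - shuf$startA, loops$endA - loops$startA)
  expect_equal(shuf$endB - shuf$startB, loops$endB - loops$startB)
  expect_equal(shuf$startB - shuf$startA, loops$startB - loops$startA)
  expect_equal(table(shuf$chromA), table(loops$chromA))
  expect_true(all(shuf$startA >= 0))
  expect_true(all(shuf$endB <= b$chrom_lengths[shuf$chromB]))

  too_big <- data.table(chromA = "chr1", startA = 0L, endA = 1000L,
                        chromB = "chr1", startB = 2e6L, endB = 2000100L,
                        loop_id = "x", pet_count = 3L)
  expect_error(simulate_loops_null(too_big, c(chr1 = 1e6), b$eqtls,
                                   call_promoter_regions(b$genes), reps = 2),
               "span")
})

test_that("planted eQTL enrichment is detected against the simulated null", {
  b <- default_bundle()
  pets <- categorize_pets(b$pets)
  loops <- call_loops(pets[category == "inter_ligation"], b$peaks$H3K4me3)
  proms <- call_promoter_regions(b$genes, chrom_lengths = b$chrom_lengths)
  enr <- simulate_loops_null(loops, b$chrom_lengths, b$eqtls, proms,
                             reps = 100, seed = 8)
  ## the null's fast pair counter agrees with the general overlap path
  expect_equal(enr$observed,
               sum(eqtl_loop_overlap(b$eqtls, loops, proms)$looped))
  expect_lt(enr$empirical_p, 0.05)
  expect_gt(enr$observed, mean(enr$null_counts))
})

test_that("GWAS window arithmetic and planted element enrichment", {
  de <- data.table(element_id = c("d1", "d2"), chrom = "chr1",
                   start = c(110000L, 400000L), end = c(110500L, 400500L))
  ## SNP at 200000: 200-kb window spans [100000, 300000)
  snps <- data.table(snp_chrom = "chr1", snp_pos = 200000L)
  hit <- regloops:::overlaps_any(de, regloops:::snp_windows(snps, 200000L))
  expect_equal(hit, c(TRUE, FALSE))  # 90 kb away in, 200 kb away out

  b <- default_bundle()
  pets <- categorize_pets(b$pets)
  loops <- call_loops(pets[category == "inter_ligation"], b$peaks$H3K4me3)
  proms <- call_promoter_regions(b$genes, chrom_lengths = b$chrom_lengths)
  lumrs <- call_lumrs(b$methylation)
  els <- call_distal_elements(b$peaks$MNase_heavy, b$peaks$MNase_light,
                              b$genes, b$peaks$H3K4me3, lumrs)
  lc <- classify_loops(loops, proms, els)
  inter <- els$element_id %in% classify_distal_elements(lc)$element_id
  enr <- gwas_element_enrichment(els, inter, b$gwas_snps, b$chrom_lengths,
                                 reps = 100, seed = 3)
  expect_lt(enr$empirical_p, 0.05)
  expect_gt(enr$hit_rate_interacting, enr$hit_rate_random)
})

test_that("category correlation contrasts exclude self-pairs and see planted sharing", {
  ## PDI-heavy bundle: every planted element targets two genes, one of which
  ## stays free of eQTL association (the planted interacting gene)
  b <- generate_bundle(synth_config(
    seed = 23, n_planted_loops = 60, ppi_fraction = 0.2, pdi_fraction = 0.6,
    pdi_multi_fraction = 1, n_planted_lumrs = 25, n_extra_distal = 3,
    n_eqtls = 120, eqtl_loop_link_fraction = 0.6))
  pets <- categorize_pets(b$pets)
  loops <- call_loops(pets[category == "inter_ligation"], b$peaks$H3K4me3)
  proms <- call_promoter_regions(b$genes, chrom_lengths = b$chrom_lengths)
  ov <- eqtl_loop_overlap(b$eqtls, loops, proms)
  calls <- classify_eqtl_genes(ov, loops, proms, b$genes)
  ## pair genes at locus scale: two <= 100-kb loops at one element put the
  ## planted partner genes within ~200 kb of each other
  cc <- category_correlation_contrast(calls, b$expression, genes = b$genes,
                                      max_pair_distance = 250e3, seed = 2)
  expect_true("eqtl_interacting_gene:looped_gene" %in% names(cc$correlations))
  ## no self-pairs anywhere
  expect_false(any(vapply(cc$correlations, function(v) any(v > 0.999999), logical(1))))
  ## interacting genes share the looped genes' latent factor: their pairs are
  ## more correlated than random:looped pairs
  expect_gt(mean(cc$correlations[["eqtl_interacting_gene:looped_gene"]]),
            mean(cc$correlations[["random_gene:looped_gene"]]))
  p <- cc$wilcoxon_p["eqtl_interacting_gene:looped_gene", "random_gene:looped_gene"]
  expect_lt(p, 0.05)
})
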