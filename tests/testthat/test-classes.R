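test_that("loops are labeled PPI/PDI/other per anchor contents", {
  genes <- mk_genes(tss = c(20000, 60000, 120000), strand = "+")
  proms <- call_promoter_regions(genes)
  de <- data.table(element_id = "d1", chrom = "chr1",
                   start = 150000L, end = 150600L)
  loops <- data.table(
    chromA = "chr1",
    startA = c(19500L, 19000L, 149900L, 200000L),
    endA   = c(20500L, 20200L, 150500L, 201000L),
    chromB = "chr1",
    startB = c(59500L, 20500L, 119500L, 300000L),
    endB   = c(60500L, 21400L, 120500L, 301000L),
    pet_count = 3L, loop_id = sprintf("l%d", 1:4)
  )
  lc <- classify_loops(loops, proms, de)
  ## l1: promoters of g1 and g2 -> PPI; l2: both anchors in g1's promoter only
  ## -> other; l3: element to g3's promoter -> PDI; l4: nothing -> other
  expect_equal(lc$label, c("PPI", "other", "PDI", "other"))
  expect_equal(lc[1]$gene_ids_A, "g1")
  expect_equal(lc[3]$distal_ids, "d1")
})

test_that("PPI precedence over PDI holds unless dual labels are requested", {
  genes <- mk_genes(tss = c(20000, 60000), strand = "+")
  proms <- call_promoter_regions(genes)
  ## element overlapping g2's promoter anchor: loop qualifies as both
  de <- data.table(element_id = "d1", chrom = "chr1", start = 59400L, end = 60000L)
  loops <- data.table(chromA = "chr1", startA = 19500L, endA = 20500L,
                      chromB = "chr1", startB = 59500L, endB = 60500L,
                      pet_count = 3L, loop_id = "l1")
  expect_equal(classify_loops(loops, proms, de)$label, "PPI")
  expect_equal(classify_loops(loops, proms, de, dual_labels = TRUE)$label, "PPI+PDI")
})

test_that("gene categories anchor/basal/other are a total partition", {
  b <- default_bundle()
  pets <- categorize_pets(b$pets)
  loops <- call_loops(pets[category == "inter_ligation"], b$peaks$H3K4me3)
  proms <- call_promoter_regions(b$genes, chrom_lengths = b$chrom_lengths)
  cats <- classify_genes(b$genes, proms, loops,
                         rbind(b$peaks$H3K4me3, b$peaks$RNAPII))
  expect_equal(nrow(cats), nrow(b$genes))
  expect_true(all(cats$category %in% c("anchor", "basal", "other")))
  ## all planted loop genes are anchor genes
  planted <- setdiff(unique(c(b$manifest$loops$geneA, b$manifest$loops$geneB)), NA)
  expect_true(all(cats[gene_id %in% planted]$category == "anchor"))
})

test_that("distal elements count distinct target genes, not loops", {
  mk_lc <- function(el, genes_by_loop) {
    rbindlist(lapply(seq_along(genes_by_loop), function(i) {
      data.table(label = "PDI", distal_ids = el[i],
                 gene_ids_A = "", gene_ids_B = genes_by_loop[i],
                 loop_id = sprintf("l%d", i), pet_count = 3L)
    }))
  }
  ## elements with target gene sets of sizes 1, 1, 2, 3; element e2 reaches
  ## its single gene via two separate loops
  lc <- mk_lc(c("e1", "e2", "e2", "e3", "e3", "e4", "e4", "e4"),
              c("g1", "g2", "g2", "g3", "g4", "g5", "g6", "g7"))
  cls <- classify_distal_elements(lc)
  expect_equal(cls[element_id == "e2"]$label, "single")
  expect_equal(sum(cls$label == "single"), 2L)
  expect_equal(sum(cls$label == "multiple"), 2L)
  expect_equal(nrow(cls), 4L)
})

test_that("anchor peaks test detects a planted intensity shift", {
  set.seed(9)
  loops <- data.table(chromA = "chr1", startA = 10000L, endA = 11000L,
                      chromB = "chr1", startB = 500000L, endB = 501000L)
  n <- 500
  anchor_peaks <- mk_peaks(rep(10100, n), rep(10900, n),
                           intensity = rnorm(n, 10, 1))
  far_peaks <- mk_peaks(seq(2e6, 3e6, length.out = n),
                        seq(2e6, 3e6, length.out = n) + 500,
                        intensity = rnorm(n, 5, 1))
  res <- compare_anchor_peak_intensity(rbind(anchor_peaks, far_peaks), loops)
  meds <- setNames(res$summary$median, res$summary$group)
  expect_true(abs((meds["anchor"] - meds["non_anchor"]) - 5) < 0.5)
  expect_lt(res$p_value, 0.01)

  ## identical groups: no signal
  same <- rbind(mk_peaks(rep(10100, 20), rep(10900, 20), intensity = 1:20),
                mk_peaks(seq(2e6, 2.1e6, length.out = 20),
                         seq(2e6, 2.1e6, length.out = 20) + 500, intensity = 1:20))
  expect_gt(suppressWarnings(compare_anchor_peak_intensity(same, loops))$p_value, 0.99)
  expect_error(compare_anchor_peak_intensity(anchor_peaks, loops), "empty")
})

test_that("network degrees match a brute-force incidence count", {
  set.seed(7)
  for (trial in 1:50) {
    n_nodes <- sample(5:25, 1)
    n_edges <- sample(4:30, 1)
    e <- data.table(gene1 = sprintf("g%d", sample(n_nodes, n_edges, replace = TRUE)),
                    gene2 = sprintf("g%d", sample(n_nodes, n_edges, replace = TRUE)))
    e <- unique(e[gene1 != gene2])
    k1 <- pmin(e$gene1, e$gene2); k2 <- pmax(e$gene1, e$gene2)
    e <- unique(data.table(gene1 = k1, gene2 = k2))
    if (!nrow(e)) next
    lc <- e[, .(label = "PPI", loop_id = sprintf("l%d", .I), pet_count = 6L,
                gene_ids_A = gene1, gene_ids_B = gene2, distal_ids = "")]
    net <- build_ppi_network(lc)
    deg <- degree_expression_summary(net)
    oracle <- oracle_degrees(e)
    expect_equal(setNames(deg$degree, deg$gene_id)[names(oracle)], oracle)
  }
})

test_that("subnetworks require PET count strictly greater than the cutoff", {
  lc <- data.table(
    label = "PPI", loop_id = c("l1", "l2"), pet_count = c(4L, 5L),
    gene_ids_A = c("g1", "g3"), gene_ids_B = c("g2", "g4"), distal_ids = ""
  )
  net <- build_ppi_network(lc)
  top <- top_subnetworks(net, n = 10, min_pet_count = 4)
  expect_equal(nrow(top), 1L)
  expect_equal(top$gene_ids, "g3,g4")
})

test_that("loop support bookkeeping sums the support classes", {
  loops <- data.table(peak_support = c(rep("both", 4), rep("one", 6)))
  s <- loop_support_summary(loops)
  expect_equal(unname(s$counts["both"] + s$counts["one"]), s$total)
})
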