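test_that("promoter windows are strand-aware and clipped", {
  genes <- mk_genes(tss = c(100000, 60000, 1000), strand = c("+", "-", "+"))
  pr <- call_promoter_regions(genes)
  expect_equal(pr[gene_id == "g1", .(start, end)], data.table(start = 98000L, end = 101500L))
  expect_equal(pr[gene_id == "g2", .(start, end)], data.table(start = 58500L, end = 62000L))
  expect_equal(pr[gene_id == "g3", .(start, end)], data.table(start = 0L, end = 2500L))
  expect_error(call_promoter_regions(mk_genes(5000, strand = "*")), "strand")
})

test_that("LUMR bins use strict thresholds with weighted means", {
  ## one bin per condition; sites at 3 contexts each
  mk_bin <- function(base, cg, chg, chh) {
    mk_meth(pos = base + c(10, 50, 90), context = c("CG", "CHG", "CHH"),
            level = c(cg, chg, chh), coverage = 100L)
  }
  calls <- rbind(
    mk_bin(0, 0.15, 0.05, 0.03),     # passes
    mk_bin(400, 0.20, 0.05, 0.03),   # CG exactly at threshold -> fails
    mk_bin(800, 0.15, 0.10, 0.03)    # CHG at threshold -> fails
  )
  lum <- call_lumrs(calls)
  expect_equal(nrow(lum), 1L)
  expect_equal(lum$start, 0L)
  expect_equal(lum$end, 200L)
})

test_that("low-coverage sites are excluded and uncovered contexts pass", {
  calls <- rbind(
    ## CG site below min coverage: bin has only a passing CHH site
    mk_meth(10, "CG", 0.9, coverage = 2L),
    mk_meth(50, "CHH", 0.01, coverage = 30L)
  )
  lum <- call_lumrs(calls, min_coverage = 3L)
  expect_equal(nrow(lum), 1L)
  expect_true(is.na(lum$mean_cg))
})

test_that("adjacent passing bins merge into planted blocks at bin resolution", {
  ## 3 hypomethylated blocks in a methylated background, dense site grid
  blocks <- data.table(start = c(10000L, 40000L, 77000L), end = c(12000L, 41000L, 80000L))
  pos <- seq(0L, 99999L, by = 25L)
  ctx <- c("CG", "CHG", "CHH")[(seq_along(pos) - 1L) %% 3L + 1L]
  in_block <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(blocks))) {
    in_block <- in_block | (pos >= blocks$start[i] & pos < blocks$end[i])
  }
  lv <- ifelse(in_block, 0.02, c(CG = 0.8, CHG = 0.6, CHH = 0.3)[ctx])
  calls <- mk_meth(pos, ctx, lv, coverage = 50L)
  lum <- call_lumrs(calls)
  expect_equal(lum[, .(start, end)], blocks)
  ## and agrees with the brute-force per-bin oracle
  expect_equal(lum[, .(chrom, start, end)], oracle_lumrs(calls))
})

test_that("distal element filters match a hand enumeration and are order-free", {
  genes <- mk_genes(tss = c(20000, 60000), strand = "+")
  proms <- call_promoter_regions(genes)
  k4 <- mk_peaks(80000, 81000)
  lumrs <- data.table(lumr_id = c("L1", "L2"),
                      chrom = "chr1",
                      start = c(100000L, 120000L), end = c(101000L, 121000L))
  heavy <- mk_peaks(
    start = c(100100, 120100, 30000, 21500, 80500, 140000),
    end   = c(100600, 120600, 30500, 22000, 81000, 140500),
    mark = "MNase_heavy"
  )
  ## p1: in L1, clear -> kept; p2: in L2 but overlapped by light -> dropped
  ## p3: in LUMR-free space -> dropped; p4: within 2 kb of gene g1 -> dropped
  ## p5: overlaps H3K4me3 -> dropped; p6: clear but no LUMR -> dropped
  light <- mk_peaks(120599, 121100, mark = "MNase_light")  # 1 bp overlap with p2
  de <- call_distal_elements(heavy, light, genes, k4, lumrs)
  expect_equal(de$source_peak_id, "p1")
  expect_equal(de$lumr_ids, "L1")

  ## order independence: shuffle heavy peak rows
  de2 <- call_distal_elements(heavy[c(4, 6, 1, 3, 5, 2)], light, genes, k4, lumrs)
  expect_equal(de2$source_peak_id, "p1")

  ## emitted elements respect the type invariants
  flanked <- genes[, .(chrom, start = start - 2000L, end = end + 2000L)]
  expect_false(any(regloops:::overlaps_any(de, flanked)))
  expect_false(any(regloops:::overlaps_any(de, k4)))
  expect_true(all(regloops:::overlaps_any(de, lumrs)))

  expect_equal(nrow(call_distal_elements(heavy[0], light, genes, k4, lumrs)), 0L)
})

test_that("signal profiles center on the TSS, flip minus strand, NA off-ends", {
  track <- list(chr1 = rep(2, 2000))  # constant coverage, 50-bp bins
  genes <- mk_genes(tss = 50000, strand = "+")
  prof <- signal_profile(genes, track, flank = 1000, bin = 50)
  expect_true(all(prof == 2))
  expect_equal(ncol(prof), 40L)

  ## region at chromosome start: upstream bins NA, not zero
  edge <- mk_genes(tss = 300, strand = "+")
  pe <- signal_profile(edge, track, flank = 1000, bin = 50)
  expect_true(anyNA(pe))
  expect_false(any(pe == 0, na.rm = TRUE))

  ## planted summit 500 bp downstream of a minus-strand TSS appears at +500
  tr <- rep(0, 2000); tss <- 50000
  tr[(tss - 500) %/% 50 + 1] <- 9  # genomically upstream-of-coordinate = downstream of minus gene
  gm <- mk_genes(tss = tss, strand = "-")
  pm <- signal_profile(gm, list(chr1 = tr), flank = 1000, bin = 50)
  offs <- as.integer(colnames(pm))
  expect_equal(offs[which(pm[1, ] == 9)], 450L)  # bin starting at +450 covers +500

  expect_error(signal_profile(genes, track, flank = 1025, bin = 50), "multiple")
})

test_that("k-means TSS states separate planted archetypes deterministically", {
  set.seed(42)
  a <- matrix(rnorm(30 * 20, mean = 0), 30, 20)
  b <- matrix(rnorm(30 * 20, mean = 8), 30, 20)
  X <- rbind(a, b)
  labs <- cluster_tss_states(list(m = X), k = 2, seed = 5)
  expect_equal(length(unique(labs[1:30])), 1L)
  expect_equal(length(unique(labs[31:60])), 1L)
  expect_true(labs[1] != labs[31])
  ## determinism and size-ordered labels
  expect_equal(labs, cluster_tss_states(list(m = X), k = 2, seed = 5))
  expect_equal(cluster_tss_states(list(m = X), k = 1, seed = 1),
               rep(1L, 60), ignore_attr = TRUE)
  expect_error(cluster_tss_states(list(m = X), k = 100, seed = 1), "exceeds")
})
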