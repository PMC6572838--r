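test_that("breadth uses a strict FPKM threshold and CV the sample SD", {
  mat <- rbind(
    g1 = c(1, 1, 1),      # exactly 1 nowhere counts as expressed
    g2 = c(2, 4, 6),
    g3 = c(5, 5, 5),
    g4 = c(0, 0, 0)
  )
  colnames(mat) <- c("t1", "t2", "t3")
  rec <- expression_breadth_and_cv(mat)
  expect_equal(rec[gene_id == "g1"]$breadth, 0L)
  expect_equal(rec[gene_id == "g2"]$cv, 0.5)  # mean 4, sample SD 2
  expect_equal(rec[gene_id == "g3"]$cv, 0)
  expect_equal(rec[gene_id == "g3"]$breadth, 3L)
  expect_false(rec[gene_id == "g4"]$cv_defined)
})

test_that("breadth and CV agree with brute-force recomputation", {
  set.seed(21)
  for (trial in 1:100) {
    m <- matrix(rexp(12 * 6), 12, 6,
                dimnames = list(sprintf("g%02d", 1:12), sprintf("t%d", 1:6)))
    rec <- expression_breadth_and_cv(m)
    orc <- oracle_breadth_cv(m)
    expect_equal(rec$breadth, orc$breadth)
    expect_equal(rec$cv, orc$cv)
  }
})

test_that("CV ranking recovers planted stable and variable gene sets", {
  set.seed(4)
  stable <- matrix(rnorm(50 * 20, mean = 100, sd = 1), 50, 20)
  variable <- matrix(rexp(50 * 20, rate = 1 / 10), 50, 20)
  mat <- rbind(stable, variable)
  rownames(mat) <- sprintf("g%03d", 1:100)
  colnames(mat) <- sprintf("t%d", 1:20)
  rec <- expression_breadth_and_cv(mat)
  sets <- rank_housekeeping_tissue_specific(rec, n = 50)
  expect_setequal(sets$housekeeping, sprintf("g%03d", 1:50))
  expect_setequal(sets$tissue_specific, sprintf("g%03d", 51:100))
  expect_error(rank_housekeeping_tissue_specific(rec, n = 60), "need")

  ## all-equal CV: sets decided purely by the gene-id tie-break
  flat <- matrix(rep(c(1, 2), each = 10), nrow = 10, ncol = 2)
  rownames(flat) <- sprintf("g%02d", 1:10); colnames(flat) <- c("t1", "t2")
  s2 <- rank_housekeeping_tissue_specific(expression_breadth_and_cv(flat), n = 3)
  expect_equal(s2$housekeeping, c("g01", "g02", "g03"))
  expect_equal(s2$tissue_specific, c("g10", "g09", "g08"))
})

test_that("mode-B nulls preserve the log-distance histogram exactly", {
  set.seed(11)
  genes <- mk_genes(tss = sort(sample(seq(10000, 5e6, by = 1500), 400)))
  obs <- data.table(gene1 = genes$gene_id[seq(1, 100, by = 2)],
                    gene2 = genes$gene_id[seq(1, 100, by = 2) + sample(3:40, 50, TRUE)])
  obs <- obs[gene1 != gene2]
  nulls <- matched_random_pairs(obs, genes, peak_genes = genes$gene_id,
                                n_bins = 20, reps = 20, mode = "B", seed = 2)
  idx1 <- match(obs$gene1, genes$gene_id); idx2 <- match(obs$gene2, genes$gene_id)
  od <- abs(genes$tss[idx1] - genes$tss[idx2])
  breaks <- seq(min(log(od)), max(log(od)), length.out = 21)
  bin <- function(d) pmin(pmax(findInterval(log(d), breaks, rightmost.closed = TRUE), 1), 20)
  obs_hist <- tabulate(bin(od), 20)
  for (r in c(1, 10, 20)) {
    expect_equal(tabulate(bin(nulls[[r]]$distance), 20), obs_hist)
    ## no null pair equals an observed pair
    expect_equal(
      length(intersect(paste(nulls[[r]]$gene1, nulls[[r]]$gene2),
                       paste(obs$gene1, obs$gene2))), 0L)
  }
  ## determinism
  nulls2 <- matched_random_pairs(obs, genes, peak_genes = genes$gene_id,
                                 n_bins = 20, reps = 20, mode = "B", seed = 2)
  expect_equal(nulls, nulls2)
})

test_that("mode-B errors when a distance bin has no eligible candidates", {
  genes <- mk_genes(tss = c(10000, 30000, 500000, 540000))
  obs <- data.table(gene1 = c("g1", "g3"), gene2 = c("g2", "g4"))
  ## only peak genes g1 and g2: the long-distance bin has no candidate pair
  expect_error(
    matched_random_pairs(obs, genes, peak_genes = c("g1", "g2"),
                         n_bins = 5, reps = 2, mode = "B", seed = 1),
    "distance bin")
})

test_that("co-expression test recovers a planted correlation difference", {
  set.seed(5)
  nt <- 40; npairs <- 60; rho <- 0.6
  ids <- sprintf("g%03d", 1:(4 * npairs))
  m <- matrix(rnorm(length(ids) * nt), length(ids), nt, dimnames = list(ids, NULL))
  for (k in seq_len(npairs)) {
    z <- rnorm(nt)
    m[2 * k - 1, ] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(nt)
    m[2 * k, ] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(nt)
  }
  fpkm <- exp(2 + m)
  obs <- data.table(gene1 = ids[2 * seq_len(npairs) - 1], gene2 = ids[2 * seq_len(npairs)])
  null_ids <- ids[(2 * npairs + 1):(4 * npairs)]
  nulls <- lapply(1:50, function(r) {
    pick <- matrix(sample(null_ids, 2 * npairs), ncol = 2)
    data.table(gene1 = pick[, 1], gene2 = pick[, 2])
  })
  res <- coexpression_test(obs, nulls, fpkm)
  expect_true(abs(res$mean_difference - rho) < 0.12)
  expect_lt(res$empirical_p, 0.05)
  expect_lt(res$t_test_p, 1e-6)

  ## identical expression vectors give r = 1
  twin <- matrix(rep(exp(rnorm(10)), 2), 2, 10, byrow = TRUE,
                 dimnames = list(c("a", "b"), NULL))
  r1 <- coexpression_test(data.table(gene1 = "a", gene2 = "b"),
                          list(data.table(gene1 = "a", gene2 = "b")), twin)
  expect_equal(r1$observed_r, 1)
})
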