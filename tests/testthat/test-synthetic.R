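test_that("identical config and seed give a byte-identical bundle", {
  cfg <- synth_config(seed = 99, n_genes = 60L, chromosome_length = 2e6,
                      n_planted_loops = 8L, n_planted_lumrs = 8L,
                      n_extra_distal = 2L, n_noise_pets = 100L,
                      n_eqtls = 20L, n_gwas_snps = 20L, n_tissues = 10L,
                      loop_span_range = c(10000L, 60000L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(generate_bundle(cfg), d1)
  write_bundle(generate_bundle(cfg), d2)
  for (f in setdiff(list.files(d1), "genes.gff3")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  ## GFF3 carries a date header line; compare feature lines only
  skip_hdr <- function(p) grep("^#", readLines(p), value = TRUE, invert = TRUE)
  expect_identical(skip_hdr(file.path(d1, "genes.gff3")),
                   skip_hdr(file.path(d2, "genes.gff3")))

  ## and the written bundle reads back into the generated structure
  b <- generate_bundle(cfg)
  rb <- read_bundle(d1)
  expect_equal(rb$genes, b$genes)
  expect_equal(rb$pets[, .(chromA, startA, chromB, startB, count)],
               b$pets[, .(chromA, startA, chromB, startB, count)])
  expect_equal(rb$expression, b$expression)
})

test_that("planted LUMR count follows the config and blocks are hypomethylated", {
  b <- generate_bundle(synth_config(seed = 5, n_planted_lumrs = 5L,
                                    n_planted_loops = 10L, pdi_fraction = 0.2,
                                    n_extra_distal = 1L, n_genes = 100L,
                                    chromosome_length = 4e6, n_noise_pets = 50L,
                                    n_tissues = 8L, n_eqtls = 10L, n_gwas_snps = 10L))
  expect_equal(nrow(b$manifest$lumrs), 5L)
  ## per planted block, pooled levels sit below the calling thresholds
  meth <- b$methylation
  for (i in seq_len(5)) {
    blk <- b$manifest$lumrs[i]
    rows <- meth[chrom == blk$chrom & pos >= blk$start & pos < blk$end]
    lev <- rows[, .(l = sum(n_meth) / sum(n_total)), by = context]
    expect_lt(lev[context == "CG"]$l, 0.2)
    expect_lt(lev[context == "CHG"]$l, 0.1)
    expect_lt(lev[context == "CHH"]$l, 0.1)
  }
})

test_that("planted looped pairs carry the configured co-expression", {
  ## >= 200 pairs across three chromosomes; empirical mean r within 0.1 of rho
  b <- generate_bundle(synth_config(
    seed = 17, n_chromosomes = 3L, n_genes = 900L, n_planted_loops = 320L,
    ppi_fraction = 0.7, pdi_fraction = 0.1, n_planted_lumrs = 40L,
    n_extra_distal = 4L, n_noise_pets = 200L, meth_site_spacing = 400L,
    n_eqtls = 40L, n_gwas_snps = 40L))
  pairs <- b$manifest$coexpr_pairs
  expect_gte(nrow(pairs), 200L)
  lm <- log1p(b$expression)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    cor(lm[pairs$gene1[i], ], lm[pairs$gene2[i], ])
  }, numeric(1))
  expect_lt(abs(mean(r) - 0.6), 0.1)
})

test_that("loop expansion to PETs honors jitter bounds", {
  loop <- data.table(chromA = "chr1", startA = 1000L, endA = 2000L,
                     chromB = "chr1", startB = 51000L, endB = 52000L)
  p0 <- expand_loop_to_pets(loop, 3, anchor_jitter = 0)
  expect_equal(nrow(p0), 3L)
  expect_equal(length(unique(p0$startA)), 1L)
  expect_equal(unique(p0$startA + 50L), 1500L)  # tag centered on anchor midpoint
  pj <- expand_loop_to_pets(loop, 20)
  expect_true(all(pj$startA >= 1000 & pj$endA <= 2000))
  expect_true(all(pj$startB >= 51000 & pj$endB <= 52000))
  expect_error(expand_loop_to_pets(loop, 0), "n_pets")
  expect_error(expand_loop_to_pets(loop, 3, anchor_jitter = 5000), "jitter")
})

test_that("impossible gene packing raises an error", {
  expect_error(generate_bundle(synth_config(n_genes = 500L, chromosome_length = 1e6,
                                            loop_span_range = c(10000L, 50000L))),
               "do not fit")
})

test_that("manifest objects are all represented in the emitted files", {
  b <- default_bundle()
  ## every planted loop has at least 3 supporting PETs among emitted PETs
  for (i in sample(nrow(b$manifest$loops), 5)) {
    lp <- b$manifest$loops[i]
    inA <- b$pets[chromA == lp$chromA & startA >= lp$startA & endA <= lp$endA]
    expect_gte(nrow(inA[startB >= lp$startB & endB <= lp$endB]), 3L)
  }
  ## every planted element is a heavy MNase peak
  hv <- b$peaks$MNase_heavy
  for (i in seq_len(nrow(b$manifest$distal_elements))) {
    el <- b$manifest$distal_elements[i]
    expect_true(any(hv$chrom == el$chrom & hv$start == el$start & hv$end == el$end))
  }
  ## eQTL and GWAS tables match the manifest row counts
  expect_equal(nrow(b$eqtls), nrow(b$manifest$eqtls))
  expect_equal(nrow(b$gwas_snps), nrow(b$manifest$gwas_snps))
})
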