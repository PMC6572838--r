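## eQTL / GWAS integration: SNP annotation, eQTL-loop overlap, gene
## categories relative to eQTLs, and enrichment against simulated-loop and
## random-region null models.

#' Annotate SNPs by genomic context
#'
#' Each SNP is assigned exactly one category with precedence
#' promoter_proximal > distal_element > gene_body > intergenic.
#'
#' @param snps data.table with `snp_chrom`, `snp_pos`.
#' @param promoters promoter table.
#' @param distal_elements distal element table.
#' @param genes gene table.
#' @return data.table with the input columns plus `category`.
#' @export
annotate_snps <- function(snps, promoters, distal_elements, genes) {
  snps <- as.data.table(copy(snps))
  pts <- snps[, .(chrom = snp_chrom, start = snp_pos, end = snp_pos + 1L)]
  in_prom <- overlaps_any(pts, as.data.table(promoters))
  in_de <- overlaps_any(pts, as.data.table(distal_elements))
  in_gene <- overlaps_any(pts, as.data.table(genes))
  snps[, category := fifelse(in_prom, "promoter_proximal",
                      fifelse(in_de, "distal_element",
                       fifelse(in_gene, "gene_body", "intergenic")))]
  snps[]
}

## window of width `window` bp centered on each SNP, clipped at 0
snp_windows <- function(snps, window) {
  half <- as.integer(window %/% 2)
  data.table(chrom = snps$snp_chrom,
             start = pmax(0L, snps$snp_pos - half),
             end = snps$snp_pos + half)
}

#' Overlap eQTL-etrait pairs with chromatin loops
#'
#' An eQTL-etrait pair is "looped" when one loop anchor overlaps the window
#' of `snp_window` bp centered on the top SNP and the other anchor overlaps
#' the promoter-proximal region of the etrait gene.
#'
#' @param eqtls eQTL table (`snp_chrom`, `snp_pos`, `gene_id`, `type`).
#' @param loops loop table.
#' @param promoters promoter table.
#' @param snp_window window width centered on the SNP (default 4000, i.e.
#'   SNP +/- 2 kb).
#' @return eQTL table with added `looped` flag and `loop_ids`
#'   (comma-separated supporting loops).
#' @export
eqtl_loop_overlap <- function(eqtls, loops, promoters, snp_window = 4000L) {
  eqtls <- as.data.table(copy(eqtls))
  loops <- as.data.table(loops)
  promoters <- as.data.table(promoters)
  n <- nrow(eqtls)
  if (!n || !nrow(loops)) {
    eqtls[, `:=`(looped = logical(.N), loop_ids = character(.N))]
    return(eqtls[])
  }
  wins <- snp_windows(eqtls, snp_window)
  ancA <- loops[, .(chrom = chromA, start = startA, end = endA)]
  ancB <- loops[, .(chrom = chromB, start = startB, end = endB)]
  ## SNP window x anchor hits
  wA <- interval_hits(wins, ancA); wB <- interval_hits(wins, ancB)
  ## etrait promoter x anchor hits, per eQTL row
  prom_idx <- match(eqtls$gene_id, promoters$gene_id)
  if (anyNA(prom_idx)) stop("eqtl_loop_overlap: etrait gene without promoter region")
  proms <- promoters[prom_idx]
  pA <- interval_hits(proms, ancA); pB <- interval_hits(proms, ancB)
  ## looped if (window~A and promoter~B) or (window~B and promoter~A) for one loop
  keyWA <- paste(wA$q_idx, wA$s_idx); keyWB <- paste(wB$q_idx, wB$s_idx)
  keyPA <- paste(pA$q_idx, pA$s_idx); keyPB <- paste(pB$q_idx, pB$s_idx)
  hits1 <- intersect(keyWA, keyPB)
  hits2 <- intersect(keyWB, keyPA)
  supp <- data.table(pair_key = c(hits1, hits2))
  eqtls[, `:=`(looped = FALSE, loop_ids = "")]
  if (nrow(supp)) {
    parts <- tstrsplit(supp$pair_key, " ", fixed = TRUE)
    sup_dt <- unique(data.table(q = as.integer(parts[[1]]), l = as.integer(parts[[2]])))
    agg <- sup_dt[, .(loop_ids = paste(loops$loop_id[sort(l)], collapse = ",")), by = q]
    eqtls[agg$q, `:=`(looped = TRUE, loop_ids = agg$loop_ids)]
  }
  eqtls[]
}

#' Classify genes relative to eQTLs
#'
#' Categories: `eqtl_gene` (eQTL-associated, not looped to its eQTL),
#' `looped_gene` (eQTL-associated and looped), `eqtl_interacting_gene`
#' (not associated with any eQTL, but its promoter is connected to an eQTL
#' SNP window by a loop). A `random_gene` control set of matching size is
#' drawn from genes in none of the first three categories, distance-matched
#' (distance to the nearest eQTL SNP) to the interacting genes via log-bin
#' sampling.
#'
#' @param eqtls output of [eqtl_loop_overlap()] (with `looped` flag).
#' @param loops loop table.
#' @param promoters promoter table.
#' @param genes gene table.
#' @param snp_window as in [eqtl_loop_overlap()].
#' @param seed RNG seed for the random control draw.
#' @param n_bins log-distance bins for the random control (default 20).
#' @return data.table with `gene_id`, `category`.
#' @export
classify_eqtl_genes <- function(eqtls, loops, promoters, genes,
                                snp_window = 4000L, seed = 1L, n_bins = 20L) {
  eqtls <- as.data.table(eqtls)
  promoters <- as.data.table(promoters)
  genes <- as.data.table(genes)
  assoc <- unique(eqtls$gene_id)
  looped <- unique(eqtls[looped == TRUE]$gene_id)
  ## genes whose promoter overlaps a loop anchor whose partner anchor
  ## overlaps an eQTL SNP window
  loops <- as.data.table(loops)
  inter <- character(0)
  if (nrow(loops) && nrow(eqtls)) {
    wins <- snp_windows(eqtls, snp_window)
    ancA <- loops[, .(chrom = chromA, start = startA, end = endA)]
    ancB <- loops[, .(chrom = chromB, start = startB, end = endB)]
    winA <- unique(interval_hits(wins, ancA)$s_idx)  # loops whose A anchor hits a window
    winB <- unique(interval_hits(wins, ancB)$s_idx)
    pA <- interval_hits(promoters, ancA)
    pB <- interval_hits(promoters, ancB)
    inter <- union(
      promoters$gene_id[pB[s_idx %in% winA]$q_idx],  # promoter at B, window at A
      promoters$gene_id[pA[s_idx %in% winB]$q_idx]
    )
    inter <- setdiff(inter, assoc)
  }
  cat <- data.table(gene_id = genes$gene_id, category = "none")
  cat[gene_id %in% assoc, category := "eqtl_gene"]
  cat[gene_id %in% looped, category := "looped_gene"]
  cat[gene_id %in% inter, category := "eqtl_interacting_gene"]
  ## distance-matched random control from unclassified genes
  if (length(inter)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    nearest_snp_dist <- function(ids) {
      idx <- match(ids, genes$gene_id)
      vapply(idx, function(i) {
        same <- eqtls[snp_chrom == genes$chrom[i]]
        if (!nrow(same)) return(NA_real_)
        min(abs(same$snp_pos - genes$tss[i]))
      }, numeric(1))
    }
    d_inter <- nearest_snp_dist(inter)
    pool_ids <- cat[category == "none"]$gene_id
    d_pool <- nearest_snp_dist(pool_ids)
    ok <- !is.na(d_pool) & d_pool > 0
    pool_ids <- pool_ids[ok]; d_pool <- d_pool[ok]
    d_inter_ok <- d_inter[!is.na(d_inter) & d_inter > 0]
    if (length(pool_ids) && length(d_inter_ok)) {
      lo <- min(log(d_inter_ok)); hi <- max(log(d_inter_ok))
      breaks <- if (hi > lo) seq(lo, hi, length.out = n_bins + 1L) else c(lo - 1, hi + 1)
      bin_of <- function(d) pmin(pmax(findInterval(log(d), breaks, rightmost.closed = TRUE), 1L),
                                 length(breaks) - 1L)
      want <- table(bin_of(d_inter_ok))
      pool_bin <- bin_of(d_pool)
      picks <- character(0)
      for (b in names(want)) {
        avail <- pool_ids[pool_bin == as.integer(b)]
        if (!length(avail)) avail <- pool_ids  # fall back to whole pool
        picks <- c(picks, sample(avail, min(want[[b]], length(avail))))
      }
      cat[gene_id %in% unique(picks), category := "random_gene"]
    }
  }
  cat[]
}

## re-place every intra-chromosomal loop uniformly at random on its own
## chromosome, preserving span and both anchor widths (uniform placement of
## the whole anchorA..anchorB footprint)
shuffle_loops <- function(loops, chrom_lengths) {
  loops <- as.data.table(loops)
  lens <- chrom_lengths[loops$chromA]
  extent <- loops$endB - loops$startA
  wA <- loops$endA - loops$startA
  offB <- loops$startB - loops$startA
  wB <- loops$endB - loops$startB
  newA <- as.integer(floor(runif(nrow(loops), 0, lens - extent)))
  shuf <- copy(loops)
  shuf[, `:=`(startA = newA, endA = newA + wA,
              startB = newA + offB, endB = newA + offB + wB)]
  shuf[]
}

## count looped eQTL-etrait pairs for a given loop table (internal, used by
## the simulated-loop null). Uses dense boolean outer comparisons, which are
## fast at the problem sizes the null simulation handles.
count_looped_pairs <- function(eqtls, loops, promoters, snp_window) {
  if (!nrow(eqtls) || !nrow(loops)) return(0L)
  wins <- snp_windows(eqtls, snp_window)
  prom_idx <- match(eqtls$gene_id, promoters$gene_id)
  if (anyNA(prom_idx)) stop("count_looped_pairs: etrait gene without promoter region")
  proms <- promoters[prom_idx]
  ovl <- function(qc, qs, qe, sc, ss, se) {
    outer(qs, se, "<") & outer(qe, ss, ">") & outer(qc, sc, "==")
  }
  WA <- ovl(wins$chrom, wins$start, wins$end, loops$chromA, loops$startA, loops$endA)
  WB <- ovl(wins$chrom, wins$start, wins$end, loops$chromB, loops$startB, loops$endB)
  PA <- ovl(proms$chrom, proms$start, proms$end, loops$chromA, loops$startA, loops$endA)
  PB <- ovl(proms$chrom, proms$start, proms$end, loops$chromB, loops$startB, loops$endB)
  sum(rowSums((WA & PB) | (WB & PA)) > 0L)
}

#' Simulated-loop null for eQTL-loop overlap
#'
#' Per replicate, every intra-chromosomal loop is re-placed uniformly at
#' random on its own chromosome, preserving its span and both anchor widths
#' (placements falling off the chromosome are resampled), and the number of
#' looped eQTL-etrait pairs is recomputed. The empirical p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (reps + 1)`; a two-sided
#' one-sample t-test of the null counts against the observed count is also
#' reported.
#'
#' @param loops intra-chromosomal loop table.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param eqtls eQTL table.
#' @param promoters promoter table.
#' @param snp_window as in [eqtl_loop_overlap()].
#' @param reps simulation replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `observed`, `null_counts`, `empirical_p`, `t_test_p`,
#'   `effect` (observed / mean(null)).
#' @export
simulate_loops_null <- function(loops, chrom_lengths, eqtls, promoters,
                                snp_window = 4000L, reps = 1000L, seed = 1L) {
  loops <- as.data.table(loops)
  loops <- loops[chromA == chromB]
  if (!nrow(loops)) stop("simulate_loops_null: no intra-chromosomal loops")
  lens <- chrom_lengths[loops$chromA]
  if (anyNA(lens)) stop("simulate_loops_null: chromosome missing from chrom_lengths")
  extent <- loops$endB - loops$startA  # total footprint start of A .. end of B
  if (any(extent >= lens)) stop("simulate_loops_null: loop span exceeds chromosome length")
  observed <- count_looped_pairs(eqtls, loops, promoters, snp_window)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_counts <- integer(reps)
  for (r in seq_len(reps)) {
    shuf <- shuffle_loops(loops, chrom_lengths)
    null_counts[r] <- count_looped_pairs(eqtls, shuf, promoters, snp_window)
  }
  tt <- if (sd(null_counts) > 0) t.test(null_counts, mu = observed)$p.value else NA_real_
  list(observed = observed,
       null_counts = null_counts,
       empirical_p = (1 + sum(null_counts >= observed)) / (reps + 1),
       t_test_p = tt,
       effect = if (mean(null_counts) > 0) observed / mean(null_counts) else NA_real_)
}

#' GWAS window enrichment of interacting distal elements
#'
#' An element "hits" a SNP when it overlaps (>= 1 bp) the window of `window`
#' bp centered on the SNP. Compares the hit rate of PDI-interacting distal
#' elements against non-interacting elements and against length- and
#' chromosome-matched random regions (uniform placement, same widths, one
#' set per replicate). The empirical p-value compares the interacting
#' elements' hit count with the random-region null counts (add-one
#' estimator); a t-test of the null counts against the observed count is
#' also reported.
#'
#' @param distal_elements distal element table.
#' @param interacting logical vector: does each element participate in a
#'   PDI?
#' @param gwas_snps data.table with `snp_chrom`, `snp_pos`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window window width centered on each SNP (default 200000).
#' @param reps random-region replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `hit_rate_interacting`, `hit_rate_non_interacting`,
#'   `hit_rate_random`, `observed`, `null_counts`, `empirical_p`,
#'   `t_test_p`.
#' @export
gwas_element_enrichment <- function(distal_elements, interacting, gwas_snps,
                                    chrom_lengths, window = 200000L,
                                    reps = 1000L, seed = 1L) {
  de <- as.data.table(distal_elements)
  stopifnot(length(interacting) == nrow(de))
  wins <- snp_windows(as.data.table(gwas_snps), window)
  hit <- overlaps_any(de, wins)
  inter_de <- de[interacting == TRUE]
  if (!nrow(inter_de)) stop("gwas_element_enrichment: no interacting elements")
  observed <- sum(hit[interacting])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lens <- chrom_lengths[inter_de$chrom]
  if (anyNA(lens)) stop("gwas_element_enrichment: chromosome missing from chrom_lengths")
  w <- inter_de$end - inter_de$start
  null_counts <- integer(reps)
  for (r in seq_len(reps)) {
    s <- as.integer(floor(runif(nrow(inter_de), 0, lens - w)))
    rnd <- data.table(chrom = inter_de$chrom, start = s, end = s + w)
    null_counts[r] <- sum(overlaps_any(rnd, wins))
  }
  tt <- if (sd(null_counts) > 0) t.test(null_counts, mu = observed)$p.value else NA_real_
  list(
    hit_rate_interacting = mean(hit[interacting]),
    hit_rate_non_interacting = if (any(!interacting)) mean(hit[!interacting]) else NA_real_,
    hit_rate_random = mean(null_counts) / nrow(inter_de),
    observed = observed,
    null_counts = null_counts,
    empirical_p = (1 + sum(null_counts >= observed)) / (reps + 1),
    t_test_p = tt
  )
}

#' Expression correlation contrasts between eQTL gene categories
#'
#' For each requested pairing of gene categories (by default the five
#' standard ones: eQTL:eQTL, eQTL:Loop, eQTL_interacting:Loop, Random:Loop,
#' Random:eQTL_interacting), samples cross-category gene pairs (self-pairs
#' excluded), computes the Pearson expression correlation per pair, and
#' reports pairwise two-sided Wilcoxon rank-sum p-values between pairings.
#'
#' @param calls output of [classify_eqtl_genes()].
#' @param matrix genes x tissues FPKM matrix.
#' @param genes optional gene table; when given, cross-category pairs are
#'   restricted to the same chromosome within `max_pair_distance` bp
#'   (TSS-to-TSS), so that pairings compare genes of the same locus scale.
#' @param pairings list of 2-element character vectors of categories.
#' @param max_pair_distance maximum TSS distance for a pair when `genes` is
#'   supplied (default 1 Mb).
#' @param max_pairs_per_contrast cap on sampled pairs per pairing
#'   (default 2000).
#' @param seed RNG seed.
#' @param log_transform correlate `log1p(FPKM)` (default TRUE).
#' @return list with `correlations` (named list of numeric vectors) and
#'   `wilcoxon_p` (matrix of pairwise p-values).
#' @export
category_correlation_contrast <- function(calls, matrix, genes = NULL,
                                          pairings = list(
                                            c("eqtl_gene", "eqtl_gene"),
                                            c("eqtl_gene", "looped_gene"),
                                            c("eqtl_interacting_gene", "looped_gene"),
                                            c("random_gene", "looped_gene"),
                                            c("random_gene", "eqtl_interacting_gene")),
                                          max_pair_distance = 1e6,
                                          max_pairs_per_contrast = 2000L,
                                          seed = 1L, log_transform = TRUE) {
  calls <- as.data.table(calls)
  m <- if (log_transform) log1p(matrix) else matrix
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  get_cat <- function(cc) intersect(calls[category == cc]$gene_id, rownames(m))
  cors <- list()
  for (p in pairings) {
    g1 <- get_cat(p[1]); g2 <- get_cat(p[2])
    if (!length(g1) || !length(g2)) next
    pairs <- CJ(gene1 = g1, gene2 = g2)[gene1 != gene2]
    if (p[1] == p[2]) pairs <- pairs[gene1 < gene2]
    if (!is.null(genes) && nrow(pairs)) {
      g <- as.data.table(genes)
      i1 <- match(pairs$gene1, g$gene_id); i2 <- match(pairs$gene2, g$gene_id)
      same <- !is.na(i1) & !is.na(i2) & g$chrom[i1] == g$chrom[i2] &
        abs(g$tss[i1] - g$tss[i2]) <= max_pair_distance
      pairs <- pairs[same]
    }
    if (!nrow(pairs)) next
    if (nrow(pairs) > max_pairs_per_contrast) {
      pairs <- pairs[sample.int(nrow(pairs), max_pairs_per_contrast)]
    }
    i1 <- match(pairs$gene1, rownames(m)); i2 <- match(pairs$gene2, rownames(m))
    cors[[paste(p, collapse = ":")]] <-
      vapply(seq_along(i1), function(k) cor(m[i1[k], ], m[i2[k], ]), numeric(1))
  }
  nm <- names(cors)
  wp <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j) {
      wp[i, j] <- wp[j, i] <-
        wilcox.test(cors[[i]], cors[[j]], alternative = "two.sided")$p.value
    }
  }
  list(correlations = cors, wilcoxon_p = wp)
}
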