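## Expression breadth / coefficient-of-variation analyses and co-expression
## of looped gene pairs against two random controls: same-chromosome random
## pairs (mode A) and distance- and peak-matched pairs (mode B).

#' Expression breadth and coefficient of variation per gene
#'
#' Breadth is the number of tissues with FPKM strictly greater than
#' `expressed_threshold`. CV = S / mean with the sample (n - 1) standard
#' deviation by default; genes with zero mean expression get `cv = NA`
#' and `cv_defined = FALSE`.
#'
#' @param matrix genes x tissues FPKM matrix.
#' @param expressed_threshold strict FPKM threshold for "expressed"
#'   (default 1).
#' @param population_sd use the population (n) SD instead of the sample SD.
#' @return data.table with `gene_id`, `breadth`, `mean_fpkm`, `cv`,
#'   `cv_defined`.
#' @export
expression_breadth_and_cv <- function(matrix, expressed_threshold = 1,
                                      population_sd = FALSE) {
  stopifnot(is.matrix(matrix), all(matrix >= 0))
  n <- ncol(matrix)
  if (n < 2 && !population_sd) {
    warning("expression_breadth_and_cv: single tissue, sample CV undefined")
  }
  mu <- rowMeans(matrix)
  s <- apply(matrix, 1, sd)
  if (population_sd) s <- s * sqrt((n - 1) / n)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  data.table(
    gene_id = rownames(matrix),
    breadth = as.integer(rowSums(matrix > expressed_threshold)),
    mean_fpkm = mu,
    cv = cv,
    cv_defined = mu > 0 & !is.na(cv)
  )
}

#' Rank housekeeping and tissue-specific genes by CV
#'
#' Genes with a defined CV are sorted ascending by CV with a deterministic
#' gene-id tie-break; the `n` lowest-CV genes are reported as housekeeping
#' (stably expressed) and the `n` highest-CV genes as tissue-specific.
#'
#' @param records output of [expression_breadth_and_cv()].
#' @param n genes per set (default 500).
#' @return list with character vectors `housekeeping` and
#'   `tissue_specific`.
#' @export
rank_housekeeping_tissue_specific <- function(records, n = 500L) {
  rec <- as.data.table(records)[cv_defined == TRUE]
  if (nrow(rec) < 2 * n) {
    stop(sprintf("rank_housekeeping_tissue_specific: need >= %d genes with defined CV, have %d",
                 2 * n, nrow(rec)))
  }
  setorder(rec, cv, gene_id)
  list(housekeeping = rec$gene_id[seq_len(n)],
       tissue_specific = rev(tail(rec$gene_id, n)))
}

#' Distance-matched random gene pairs
#'
#' Builds null gene-pair sets for the co-expression test. Mode `"A"` draws
#' uniformly random same-chromosome gene pairs. Mode `"B"` matches the
#' observed pairs' genomic-distance distribution: log distances (natural
#' log) of the observed pairs are split into `n_bins` equal-width bins, and
#' for every observed pair a random same-chromosome pair of peak-carrying
#' genes with log distance in the same bin is drawn. Candidates identical to
#' any observed pair are excluded up front, so the per-bin pair counts of
#' every replicate equal the observed histogram exactly.
#'
#' @param observed_pairs data.table with `gene1`, `gene2` (intra-chromosomal
#'   pairs).
#' @param genes gene table (`gene_id`, `chrom`, `tss`).
#' @param peak_genes character vector of gene ids carrying an H3K4me3 or
#'   RNAPII peak (required for mode `"B"`).
#' @param n_bins number of log-distance bins (default 20).
#' @param reps number of replicate null sets (default 1000).
#' @param mode `"A"` or `"B"`.
#' @param seed RNG seed.
#' @return list of `reps` data.tables (`gene1`, `gene2`, `distance`).
#' @export
matched_random_pairs <- function(observed_pairs, genes, peak_genes = NULL,
                                 n_bins = 20L, reps = 1000L,
                                 mode = c("B", "A"), seed = 1L) {
  mode <- match.arg(mode)
  obs <- as.data.table(observed_pairs)
  genes <- as.data.table(genes)
  stopifnot(nrow(obs) > 0, reps >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx1 <- match(obs$gene1, genes$gene_id); idx2 <- match(obs$gene2, genes$gene_id)
  if (anyNA(idx1) || anyNA(idx2)) stop("matched_random_pairs: observed gene missing from gene table")
  if (any(genes$chrom[idx1] != genes$chrom[idx2])) {
    stop("matched_random_pairs: observed pairs must be intra-chromosomal")
  }
  obs_dist <- abs(genes$tss[idx1] - genes$tss[idx2])
  if (any(obs_dist <= 0)) stop("matched_random_pairs: nonpositive pair distance")
  obs_key <- paste(pmin(obs$gene1, obs$gene2), pmax(obs$gene1, obs$gene2))

  if (mode == "A") {
    ## uniform same-chromosome pairs, resampled if equal to an observed pair
    bychrom <- split(genes$gene_id, genes$chrom)
    bychrom <- bychrom[vapply(bychrom, length, integer(1)) >= 2]
    if (!length(bychrom)) stop("matched_random_pairs: no chromosome with >= 2 genes")
    out <- vector("list", reps)
    for (r in seq_len(reps)) {
      g1 <- character(nrow(obs)); g2 <- character(nrow(obs))
      for (i in seq_len(nrow(obs))) {
        for (att in seq_len(1000L)) {
          chr <- sample(names(bychrom), 1L)
          pick <- sample(bychrom[[chr]], 2L)
          key <- paste(min(pick), max(pick))
          if (!key %in% obs_key) break
          if (att == 1000L) stop("matched_random_pairs: rejection limit reached")
        }
        g1[i] <- min(pick); g2[i] <- max(pick)
      }
      d <- abs(genes$tss[match(g1, genes$gene_id)] - genes$tss[match(g2, genes$gene_id)])
      out[[r]] <- data.table(gene1 = g1, gene2 = g2, distance = d)
    }
    return(out)
  }

  ## mode B: enumerate candidate same-chromosome pairs among peak genes
  if (is.null(peak_genes)) stop("matched_random_pairs: mode B requires peak_genes")
  pool <- genes[gene_id %in% peak_genes]
  cand <- rbindlist(lapply(split(pool, pool$chrom), function(g) {
    if (nrow(g) < 2) return(NULL)
    ij <- utils::combn(nrow(g), 2)
    data.table(gene1 = g$gene_id[ij[1, ]], gene2 = g$gene_id[ij[2, ]],
               distance = abs(g$tss[ij[1, ]] - g$tss[ij[2, ]]))
  }))
  if (is.null(cand) || !nrow(cand)) stop("matched_random_pairs: no candidate pairs")
  cand <- cand[distance > 0]
  k1 <- pmin(cand$gene1, cand$gene2); k2 <- pmax(cand$gene1, cand$gene2)
  cand[, `:=`(gene1 = k1, gene2 = k2)]
  cand <- cand[!paste(gene1, gene2) %in% obs_key]
  ## equal-width bins over the observed log-distance range
  lo <- min(log(obs_dist)); hi <- max(log(obs_dist))
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin_of <- function(d) pmin(pmax(findInterval(log(d), breaks, rightmost.closed = TRUE), 1L), n_bins)
  obs_bin <- bin_of(obs_dist)
  cand[, dist_bin := bin_of(distance)]
  cand <- cand[log(distance) >= lo & log(distance) <= hi]
  cand_by_bin <- split(seq_len(nrow(cand)), cand$dist_bin)
  need <- table(factor(obs_bin, levels = as.character(seq_len(n_bins))))
  for (b in names(need)) {
    if (need[[b]] > 0 && (is.null(cand_by_bin[[b]]) || !length(cand_by_bin[[b]]))) {
      stop(sprintf("matched_random_pairs: no eligible random pair in distance bin %s", b))
    }
  }
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    picks <- integer(length(obs_bin))
    for (b in names(need)) {
      if (need[[b]] == 0) next
      rows <- cand_by_bin[[b]]
      picks[obs_bin == as.integer(b)] <-
        rows[sample.int(length(rows), need[[b]], replace = length(rows) < need[[b]])]
    }
    out[[r]] <- cand[picks, .(gene1, gene2, distance)]
  }
  out
}

#' Co-expression of looped gene pairs versus random nulls
#'
#' Computes the Pearson correlation across tissues for every observed pair
#' and for every pair of the replicate null sets, then compares observed and
#' pooled null correlations with a two-sided two-sample t-test. An empirical
#' one-sided p-value is also reported from the per-replicate null means with
#' the add-one estimator `(1 + #{null mean >= observed mean}) / (reps + 1)`.
#'
#' @param observed_pairs data.table with `gene1`, `gene2`.
#' @param null_sets list of null pair tables ([matched_random_pairs()]).
#' @param matrix genes x tissues FPKM matrix covering all genes involved.
#' @param log_transform correlate `log1p(FPKM)` (default TRUE) rather than
#'   raw FPKM.
#' @return list with `observed_r`, `null_r` (pooled), `null_rep_means`,
#'   `mean_difference`, `t_test_p`, `empirical_p`.
#' @export
coexpression_test <- function(observed_pairs, null_sets, matrix,
                              log_transform = TRUE) {
  obs <- as.data.table(observed_pairs)
  m <- if (log_transform) log1p(matrix) else matrix
  pair_cor <- function(p) {
    i1 <- match(p$gene1, rownames(m)); i2 <- match(p$gene2, rownames(m))
    if (anyNA(i1) || anyNA(i2)) stop("coexpression_test: gene missing from expression matrix")
    vapply(seq_along(i1), function(k) cor(m[i1[k], ], m[i2[k], ]), numeric(1))
  }
  obs_r <- pair_cor(obs)
  null_r_by_rep <- lapply(null_sets, pair_cor)
  null_means <- vapply(null_r_by_rep, mean, numeric(1))
  null_r <- unlist(null_r_by_rep)
  tt <- if (length(obs_r) >= 2 && length(null_r) >= 2) {
    t.test(obs_r, null_r, alternative = "two.sided")
  } else list(p.value = NA_real_)
  list(
    observed_r = obs_r,
    null_r = null_r,
    null_rep_means = null_means,
    mean_difference = mean(obs_r) - mean(null_r),
    t_test_p = tt$p.value,
    empirical_p = (1 + sum(null_means >= mean(obs_r))) / (length(null_means) + 1)
  )
}
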