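library(data.table)

## ---- small builders --------------------------------------------------------

mk_genes <- function(tss, strand = "+", chrom = "chr1", len = 2000L) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", tss, tss - len + 1L)
  data.table(
    gene_id = sprintf("g%d", seq_len(n)),
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(start + len),
    strand = strand,
    tss = as.integer(tss)
  )
}

mk_peaks <- function(start, end, chrom = "chr1", intensity = 1,
                     mark = "H3K4me3") {
  data.table(
    peak_id = sprintf("p%d", seq_along(start)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    intensity = rep_len(intensity, length(start)), mark = mark
  )
}

mk_pairs <- function(startA, startB, chrom = "chr1", width = 100L, count = 1L) {
  data.table(
    chromA = chrom, startA = as.integer(startA),
    endA = as.integer(startA + width),
    chromB = chrom, startB = as.integer(startB),
    endB = as.integer(startB + width),
    count = as.integer(rep_len(count, length(startA))),
    source = NA_character_, peak_support = NA_character_
  )
}

## one methylation site per row at given positions, all contexts covered
mk_meth <- function(pos, context, level, coverage = 30L, chrom = "chr1") {
  data.table(
    chrom = chrom, pos = as.integer(pos), context = context,
    n_meth = as.integer(round(level * coverage)), n_total = as.integer(coverage)
  )
}

## a cached small default bundle shared by read-only tests
.bundle_cache <- new.env()
default_bundle <- function(seed = 11) {
  key <- paste0("b", seed)
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <- generate_bundle(synth_config(seed = seed))
  }
  .bundle_cache[[key]]
}

## ---- independent brute-force oracles --------------------------------------

## per-bin LUMR scan: explicit loops over bins and contexts
oracle_lumrs <- function(calls, bin_size = 200L,
                         thresholds = c(CG = 0.2, CHG = 0.1, CHH = 0.1),
                         min_coverage = 3L) {
  calls <- calls[calls$n_total >= min_coverage, ]
  out <- list()
  for (ch in sort(unique(calls$chrom))) {
    cc <- calls[calls$chrom == ch, ]
    if (!nrow(cc)) next
    bins <- sort(unique(cc$pos %/% bin_size))
    passing <- integer(0)
    for (b in bins) {
      rows <- cc[cc$pos %/% bin_size == b, ]
      ok <- TRUE
      for (ctx in c("CG", "CHG", "CHH")) {
        sub <- rows[rows$context == ctx, ]
        if (nrow(sub)) {
          lev <- sum(sub$n_meth) / sum(sub$n_total)
          if (lev >= thresholds[[ctx]]) ok <- FALSE
        }
      }
      if (ok) passing <- c(passing, b)
    }
    if (!length(passing)) next
    ## merge consecutive bins
    s <- passing[1]; prev <- passing[1]
    for (b in passing[-1]) {
      if (b == prev + 1) prev <- b
      else {
        out[[length(out) + 1]] <- data.table(chrom = ch, start = s * bin_size,
                                             end = (prev + 1) * bin_size)
        s <- b; prev <- b
      }
    }
    out[[length(out) + 1]] <- data.table(chrom = ch, start = s * bin_size,
                                         end = (prev + 1) * bin_size)
  }
  if (!length(out)) return(data.table(chrom = character(), start = integer(),
                                      end = integer()))
  rbindlist(out)[order(chrom, start)]
}

## direct per-gene breadth and CV
oracle_breadth_cv <- function(mat, thr = 1) {
  res <- data.table(gene_id = rownames(mat), breadth = 0L, cv = NA_real_)
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    res$breadth[i] <- sum(v > thr)
    m <- mean(v)
    if (m > 0) res$cv[i] <- sd(v) / m
  }
  res
}

## incidence count of degrees from an edge list
oracle_degrees <- function(edges) {
  nodes <- sort(unique(c(edges$gene1, edges$gene2)))
  deg <- setNames(integer(length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    deg[edges$gene1[r]] <- deg[edges$gene1[r]] + 1L
    deg[edges$gene2[r]] <- deg[edges$gene2[r]] + 1L
  }
  deg
}

## per-SNP category by explicit membership checks with precedence
oracle_snp_categories <- function(snps, promoters, elements, genes) {
  in_any <- function(chrom, pos, tab) {
    any(tab$chrom == chrom & tab$start <= pos & pos < tab$end)
  }
  vapply(seq_len(nrow(snps)), function(i) {
    ch <- snps$snp_chrom[i]; p <- snps$snp_pos[i]
    if (in_any(ch, p, promoters)) "promoter_proximal"
    else if (in_any(ch, p, elements)) "distal_element"
    else if (in_any(ch, p, genes)) "gene_body"
    else "intergenic"
  }, character(1))
}
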