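## Loop classification (PPI/PDI), gene and distal-element categories,
## anchor-peak intensity contrasts, and the PPI gene network.

## gene ids whose promoters overlap each of the two anchors of every loop
anchor_gene_sets <- function(loops, promoters) {
  loops <- as.data.table(loops); promoters <- as.data.table(promoters)
  hitsA <- interval_hits(loops[, .(chrom = chromA, start = startA, end = endA)], promoters)
  hitsB <- interval_hits(loops[, .(chrom = chromB, start = startB, end = endB)], promoters)
  list(
    A = split(promoters$gene_id[hitsA$s_idx], factor(hitsA$q_idx, levels = seq_len(nrow(loops)))),
    B = split(promoters$gene_id[hitsB$s_idx], factor(hitsB$q_idx, levels = seq_len(nrow(loops))))
  )
}

#' Classify loops into PPI, PDI and other
#'
#' A loop is a PPI (promoter proximal-proximal interaction) when its two
#' anchors overlap promoter-proximal regions of at least one pair of
#' *different* genes; it is a PDI (proximal-distal interaction) when one
#' anchor overlaps a distal element and the other a promoter-proximal
#' region. A loop qualifying as both is labeled PPI unless
#' `dual_labels = TRUE`, which reports `"PPI+PDI"`. Everything else is
#' `"other"`.
#'
#' @param loops loop table ([call_loops()] layout).
#' @param promoters promoter table ([call_promoter_regions()] layout).
#' @param distal_elements distal element table ([call_distal_elements()]).
#' @param dual_labels report joint PPI/PDI qualification instead of PPI
#'   precedence (default FALSE).
#' @return loop table with added `label`, `gene_ids_A`, `gene_ids_B`,
#'   `distal_ids` columns (comma-separated id lists, "" when empty).
#' @export
classify_loops <- function(loops, promoters, distal_elements, dual_labels = FALSE) {
  loops <- as.data.table(copy(loops))
  n <- nrow(loops)
  if (!n) {
    loops[, `:=`(label = character(), gene_ids_A = character(),
                 gene_ids_B = character(), distal_ids = character())]
    return(loops[])
  }
  gs <- anchor_gene_sets(loops, promoters)
  de <- as.data.table(distal_elements)
  deA <- interval_hits(loops[, .(chrom = chromA, start = startA, end = endA)], de)
  deB <- interval_hits(loops[, .(chrom = chromB, start = startB, end = endB)], de)
  dA <- split(de$element_id[deA$s_idx], factor(deA$q_idx, levels = seq_len(n)))
  dB <- split(de$element_id[deB$s_idx], factor(deB$q_idx, levels = seq_len(n)))
  label <- character(n)
  for (i in seq_len(n)) {
    gA <- unique(gs$A[[i]]); gB <- unique(gs$B[[i]])
    ## a cross-anchor pair of different genes must exist
    is_ppi <- length(gA) > 0 && length(gB) > 0 &&
      (length(union(gA, gB)) > 1 || !setequal(gA, gB))
    is_pdi <- (length(dA[[i]]) > 0 && length(gB) > 0) ||
              (length(dB[[i]]) > 0 && length(gA) > 0)
    label[i] <- if (is_ppi && is_pdi && dual_labels) "PPI+PDI"
                else if (is_ppi) "PPI"
                else if (is_pdi) "PDI"
                else "other"
  }
  loops[, label := label]
  loops[, gene_ids_A := vapply(gs$A, function(g) paste(unique(g), collapse = ","), character(1))]
  loops[, gene_ids_B := vapply(gs$B, function(g) paste(unique(g), collapse = ","), character(1))]
  loops[, distal_ids := mapply(function(x, y) paste(unique(c(x, y)), collapse = ","), dA, dB)]
  loops[]
}

#' Gene pairs connected by PPI loops
#'
#' Expands classified PPI loops into unique unordered pairs of different
#' genes, one gene from each anchor.
#'
#' @param loop_classes output of [classify_loops()].
#' @param genes optional gene table; when given, TSS-to-TSS distance is
#'   attached for intra-chromosomal pairs.
#' @return data.table with `gene1`, `gene2`, `loop_id`, `pet_count` and
#'   optionally `distance` (unique pairs keep their maximum PET count).
#' @export
ppi_gene_pairs <- function(loop_classes, genes = NULL) {
  lc <- as.data.table(loop_classes)
  lc <- lc[label %in% c("PPI", "PPI+PDI")]
  if (!nrow(lc)) {
    return(data.table(gene1 = character(), gene2 = character(),
                      loop_id = character(), pet_count = integer()))
  }
  rows <- lapply(seq_len(nrow(lc)), function(i) {
    gA <- strsplit(lc$gene_ids_A[i], ",", fixed = TRUE)[[1]]
    gB <- strsplit(lc$gene_ids_B[i], ",", fixed = TRUE)[[1]]
    gr <- expand.grid(gene1 = gA, gene2 = gB, stringsAsFactors = FALSE)
    gr <- gr[gr$gene1 != gr$gene2, , drop = FALSE]
    if (!nrow(gr)) return(NULL)
    data.table(gene1 = pmin(gr$gene1, gr$gene2), gene2 = pmax(gr$gene1, gr$gene2),
               loop_id = lc$loop_id[i], pet_count = lc$pet_count[i])
  })
  out <- rbindlist(rows)
  out <- out[, .(loop_id = loop_id[which.max(pet_count)],
                 pet_count = max(pet_count)), by = .(gene1, gene2)]
  if (!is.null(genes)) {
    g <- as.data.table(genes)
    idx1 <- match(out$gene1, g$gene_id); idx2 <- match(out$gene2, g$gene_id)
    out[, distance := ifelse(g$chrom[idx1] == g$chrom[idx2],
                             abs(g$tss[idx1] - g$tss[idx2]), NA_integer_)]
  }
  setorder(out, gene1, gene2)
  out[]
}

#' Genes carrying a ChIP peak
#'
#' Returns the ids of genes whose body or promoter-proximal region overlaps
#' at least one of the given peaks (>= 1 bp).
#'
#' @param genes gene table.
#' @param promoters promoter table.
#' @param peaks peak table (any marks).
#' @return character vector of gene ids.
#' @export
genes_with_peaks <- function(genes, promoters, peaks) {
  genes <- as.data.table(genes); promoters <- as.data.table(promoters)
  peaks <- as.data.table(peaks)
  union(genes$gene_id[overlaps_any(genes, peaks)],
        promoters$gene_id[overlaps_any(promoters, peaks)])
}

#' Classify genes into anchor, basal and other
#'
#' `anchor`: the gene's promoter-proximal region overlaps at least one loop
#' anchor. `basal`: not an anchor gene but carries an H3K4me3 or RNAPII
#' peak (gene body or promoter). `other`: neither. The three categories are
#' a total partition of the gene set.
#'
#' @param genes gene table.
#' @param promoters promoter table.
#' @param loops loop table.
#' @param peaks peak table with H3K4me3/RNAPII rows (`mark` column used when
#'   present).
#' @return data.table with `gene_id`, `category`.
#' @export
classify_genes <- function(genes, promoters, loops, peaks) {
  genes <- as.data.table(genes); promoters <- as.data.table(promoters)
  loops <- as.data.table(loops); peaks <- as.data.table(peaks)
  if ("mark" %in% names(peaks) && !all(is.na(peaks$mark))) {
    peaks <- peaks[mark %in% c("H3K4me3", "RNAPII")]
  }
  anchors <- rbind(
    loops[, .(chrom = chromA, start = startA, end = endA)],
    loops[, .(chrom = chromB, start = startB, end = endB)]
  )
  prom_anchor <- overlaps_any(promoters, anchors)
  anchor_genes <- unique(promoters$gene_id[prom_anchor])
  ## peak on gene body or promoter region marks the gene
  body_peak <- overlaps_any(genes, peaks)
  prom_peak <- overlaps_any(promoters, peaks)
  marked <- union(genes$gene_id[body_peak], promoters$gene_id[prom_peak])
  cat <- ifelse(genes$gene_id %in% anchor_genes, "anchor",
                ifelse(genes$gene_id %in% marked, "basal", "other"))
  data.table(gene_id = genes$gene_id, category = cat)
}

#' Classify distal elements by number of target genes
#'
#' Every distal element appearing in at least one PDI is classified as
#' `single` (interacts with exactly one distinct gene) or `multiple`
#' (two or more distinct genes). Genes, not loops, are counted.
#'
#' @param loop_classes output of [classify_loops()] (PDI labels used).
#' @return data.table with `element_id`, `n_target_genes`, `label`.
#' @export
classify_distal_elements <- function(loop_classes) {
  lc <- as.data.table(loop_classes)
  lc <- lc[label %in% c("PDI", "PPI+PDI")]
  if (!nrow(lc)) {
    return(data.table(element_id = character(), n_target_genes = integer(),
                      label = character()))
  }
  rows <- lapply(seq_len(nrow(lc)), function(i) {
    els <- strsplit(lc$distal_ids[i], ",", fixed = TRUE)[[1]]
    els <- els[nzchar(els)]
    gg <- unique(c(strsplit(lc$gene_ids_A[i], ",", fixed = TRUE)[[1]],
                   strsplit(lc$gene_ids_B[i], ",", fixed = TRUE)[[1]]))
    gg <- gg[nzchar(gg)]
    if (!length(els) || !length(gg)) return(NULL)
    CJ(element_id = els, gene_id = gg, unique = TRUE)
  })
  pairs <- unique(rbindlist(rows))
  out <- pairs[, .(n_target_genes = uniqueN(gene_id)), by = element_id]
  out[, label := ifelse(n_target_genes >= 2L, "multiple", "single")]
  setorder(out, element_id)
  out[]
}

#' Compare intensity of anchor versus non-anchor peaks
#'
#' Partitions peaks by overlap with loop anchors and compares intensities
#' with a two-sided Wilcoxon rank-sum (Mann-Whitney) test.
#'
#' @param peaks peak table with `intensity`.
#' @param loops loop table.
#' @return list with `summary` (per-group n, median, quartiles) and
#'   `p_value`.
#' @export
compare_anchor_peak_intensity <- function(peaks, loops) {
  peaks <- as.data.table(peaks); loops <- as.data.table(loops)
  anchors <- rbind(
    loops[, .(chrom = chromA, start = startA, end = endA)],
    loops[, .(chrom = chromB, start = startB, end = endB)]
  )
  is_anchor <- overlaps_any(peaks, anchors)
  if (!any(is_anchor) || all(is_anchor)) {
    stop("compare_anchor_peak_intensity: one of the two peak groups is empty")
  }
  grp <- list(anchor = peaks$intensity[is_anchor],
              non_anchor = peaks$intensity[!is_anchor])
  summ <- rbindlist(lapply(names(grp), function(g) {
    q <- quantile(grp[[g]], c(0.25, 0.5, 0.75))
    data.table(group = g, n = length(grp[[g]]),
               q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  }))
  wt <- wilcox.test(grp$anchor, grp$non_anchor, alternative = "two.sided")
  list(summary = summ, p_value = wt$p.value)
}

#' Build the PPI gene network
#'
#' Undirected graph over genes; one edge per unique PPI gene pair, weighted
#' by the maximum supporting PET count. Mean FPKM across tissues is attached
#' as a node attribute when an expression matrix is supplied.
#'
#' @param loop_classes output of [classify_loops()].
#' @param expression optional genes x tissues FPKM matrix.
#' @return igraph graph.
#' @export
build_ppi_network <- function(loop_classes, expression = NULL) {
  pairs <- ppi_gene_pairs(loop_classes)
  g <- igraph::graph_from_data_frame(
    pairs[, .(gene1, gene2, pet_count)], directed = FALSE)
  if (!is.null(expression)) {
    fpkm <- rowMeans(expression)[igraph::V(g)$name]
    igraph::V(g)$mean_fpkm <- unname(fpkm)
  }
  g
}

#' Per-gene degree and expression summary of the PPI network
#'
#' @param network igraph graph from [build_ppi_network()].
#' @return data.table with `gene_id`, `degree` and `mean_fpkm` when
#'   available.
#' @export
degree_expression_summary <- function(network) {
  out <- data.table(gene_id = igraph::V(network)$name,
                    degree = as.integer(igraph::degree(network)))
  if (!is.null(igraph::V(network)$mean_fpkm)) {
    out[, mean_fpkm := igraph::V(network)$mean_fpkm]
  }
  setorder(out, -degree, gene_id)
  out[]
}

#' Top PPI subnetworks
#'
#' Restricts the network to edges with PET count strictly greater than
#' `min_pet_count` and ranks the connected components of the restricted
#' graph by node count (ties by total edge PET count, then by smallest gene
#' id).
#'
#' @param network igraph graph from [build_ppi_network()].
#' @param n number of top components to return (default 100).
#' @param min_pet_count edges must have `pet_count > min_pet_count`
#'   (default 4).
#' @return data.table with `component`, `n_genes`, `n_edges`,
#'   `total_pet_count`, `gene_ids`.
#' @export
top_subnetworks <- function(network, n = 100L, min_pet_count = 4L) {
  keep <- igraph::E(network)$pet_count > min_pet_count
  sub <- igraph::subgraph_from_edges(network, igraph::E(network)[keep],
                                     delete.vertices = TRUE)
  comp <- igraph::components(sub)
  if (comp$no == 0) {
    return(data.table(component = integer(), n_genes = integer(),
                      n_edges = integer(), total_pet_count = integer(),
                      gene_ids = character()))
  }
  memb <- comp$membership
  rows <- rbindlist(lapply(seq_len(comp$no), function(ci) {
    vs <- names(memb)[memb == ci]
    sg <- igraph::induced_subgraph(sub, vs)
    data.table(n_genes = length(vs),
               n_edges = igraph::ecount(sg),
               total_pet_count = sum(igraph::E(sg)$pet_count),
               gene_ids = paste(sort(vs), collapse = ","))
  }))
  setorder(rows, -n_genes, -total_pet_count, gene_ids)
  rows[, component := .I]
  setcolorder(rows, c("component", "n_genes", "n_edges", "total_pet_count", "gene_ids"))
  head(rows, n)
}

#' Tabulate loop peak support
#'
#' Counts loops by peak support class (`both` / `one` anchors overlapping a
#' ChIP peak) and reports the total, mirroring the standard bookkeeping for
#' published loop sets.
#'
#' @param loops loop table with a `peak_support` column.
#' @return list with `counts` (named vector) and `total`.
#' @export
loop_support_summary <- function(loops) {
  loops <- as.data.table(loops)
  counts <- table(factor(loops$peak_support, levels = c("both", "one")))
  list(counts = as.vector(counts) |> setNames(names(counts)),
       total = nrow(loops))
}
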