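## Annotation of promoter-proximal regions, low/unmethylated regions (LUMRs)
## and candidate distal regulatory elements, plus TSS signal profiling and
## chromatin-state clustering.

#' Call promoter-proximal regions around gene TSSs
#'
#' A promoter-proximal region spans 2 kb upstream to 1.5 kb downstream of the
#' transcription start site, oriented by gene strand and clipped at
#' chromosome boundaries.
#'
#' @param genes data.table of gene models ([read_gff3()] layout), strand
#'   required.
#' @param upstream bp upstream of the TSS (default 2000).
#' @param downstream bp downstream of the TSS (default 1500).
#' @param chrom_lengths optional named vector of chromosome lengths used for
#'   clipping on the right.
#' @return data.table with `promoter_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
call_promoter_regions <- function(genes, upstream = 2000L, downstream = 1500L,
                                  chrom_lengths = NULL) {
  genes <- as.data.table(genes)
  stopifnot(upstream >= 0, downstream >= 0)
  if (!nrow(genes)) {
    return(data.table(promoter_id = character(), gene_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character()))
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("call_promoter_regions: gene without strand (+/- required)")
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  out <- data.table(
    promoter_id = paste0("prom_", genes$gene_id),
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(0L, as.integer(start)),
    end = as.integer(end),
    strand = genes$strand
  )
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths[out$chrom]
    if (anyNA(lens)) stop("call_promoter_regions: chromosome missing from chrom_lengths")
    out[, end := pmin(end, as.integer(lens))]
  }
  validate_intervals(out, "promoter regions")
  out[]
}

#' Call low/unmethylated methylation regions (LUMRs)
#'
#' The genome is tiled in fixed non-overlapping bins; in each bin the
#' weighted mean methylation level per context is the sum of methylated read
#' counts over the sum of total read counts across sites with coverage of at
#' least `min_coverage`. A bin passes when CG < 0.2, CHG < 0.1 and
#' CHH < 0.1 (strict inequalities); a context with no covered site in a bin
#' passes by default. Adjacent passing bins are merged into one region.
#'
#' @param calls methylation call table ([read_methylation_table()] layout).
#' @param bin_size bin width in bp (default 200).
#' @param thresholds named vector of strict upper thresholds per context.
#' @param min_coverage minimum per-site read depth for a site to count.
#' @return data.table with `lumr_id`, `chrom`, `start`, `end`,
#'   `mean_cg`, `mean_chg`, `mean_chh` (NA when no covered site).
#' @export
call_lumrs <- function(calls, bin_size = 200L,
                       thresholds = c(CG = 0.2, CHG = 0.1, CHH = 0.1),
                       min_coverage = 3L) {
  if (bin_size <= 0) stop("call_lumrs: bin_size must be positive")
  calls <- as.data.table(calls)
  empty <- data.table(lumr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      mean_cg = numeric(), mean_chg = numeric(),
                      mean_chh = numeric())
  if (!nrow(calls)) return(empty)
  calls <- calls[n_total >= min_coverage]
  if (!nrow(calls)) return(empty)
  calls[, bin := pos %/% as.integer(bin_size)]
  agg <- calls[, .(level = sum(n_meth) / sum(n_total)), by = .(chrom, bin, context)]
  wide <- dcast(agg, chrom + bin ~ context, value.var = "level")
  for (ctx in c("CG", "CHG", "CHH")) {
    if (!ctx %in% names(wide)) wide[, (ctx) := NA_real_]
  }
  ## an uncovered context passes; a covered one must be strictly below its threshold
  wide[, pass := (is.na(CG) | CG < thresholds[["CG"]]) &
         (is.na(CHG) | CHG < thresholds[["CHG"]]) &
         (is.na(CHH) | CHH < thresholds[["CHH"]])]
  passing <- wide[pass == TRUE]
  if (!nrow(passing)) return(empty)
  setorder(passing, chrom, bin)
  passing[, run := cumsum(c(1L, as.integer(diff(bin) != 1L))), by = chrom]
  regions <- passing[, .(
    start = as.integer(min(bin) * bin_size),
    end = as.integer((max(bin) + 1L) * bin_size),
    mean_cg = mean(CG, na.rm = TRUE),
    mean_chg = mean(CHG, na.rm = TRUE),
    mean_chh = mean(CHH, na.rm = TRUE)
  ), by = .(chrom, run)]
  regions[, run := NULL]
  setorder(regions, chrom, start)
  regions[, lumr_id := sprintf("lumr_%d", .I)]
  for (cl in c("mean_cg", "mean_chg", "mean_chh")) {
    regions[is.nan(get(cl)), (cl) := NA_real_]
  }
  setcolorder(regions, c("lumr_id", "chrom", "start", "end",
                         "mean_cg", "mean_chg", "mean_chh"))
  regions[]
}

#' Call candidate distal regulatory elements
#'
#' Candidates are heavy-digest MNase peaks with no overlap (>= `min_overlap`
#' bp) with any light-digest MNase peak. Candidates overlapping a gene body,
#' a gene body extended by `gene_flank` bp on both sides, or an H3K4me3 peak
#' are excluded; surviving candidates must overlap at least one LUMR.
#'
#' @param heavy_peaks,light_peaks MNase peak tables ([read_bed()] layout).
#' @param genes gene model table.
#' @param h3k4me3_peaks H3K4me3 peak table.
#' @param lumrs LUMR table ([call_lumrs()] layout).
#' @param gene_flank bp added to each side of gene bodies for the exclusion
#'   rule (default 2000).
#' @param min_overlap minimum overlap in bp for the light-peak subtraction
#'   (default 1).
#' @return data.table with `element_id`, `chrom`, `start`, `end`,
#'   `source_peak_id`, `lumr_ids` (comma-separated supporting LUMR ids).
#' @export
call_distal_elements <- function(heavy_peaks, light_peaks, genes,
                                 h3k4me3_peaks, lumrs,
                                 gene_flank = 2000L, min_overlap = 1L) {
  heavy <- as.data.table(heavy_peaks)
  empty <- data.table(element_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      source_peak_id = character(), lumr_ids = character())
  if (!nrow(heavy)) return(empty)
  keep <- rep(TRUE, nrow(heavy))
  light <- as.data.table(light_peaks)
  if (nrow(light)) keep <- keep & !overlaps_any(heavy, light, min_overlap)
  genes <- as.data.table(genes)
  if (nrow(genes)) {
    flanked <- genes[, .(chrom, start = pmax(0L, start - as.integer(gene_flank)),
                         end = end + as.integer(gene_flank))]
    ## gene body +/- flank contains the gene body itself, one exclusion pass
    keep <- keep & !overlaps_any(heavy, flanked)
  }
  k4 <- as.data.table(h3k4me3_peaks)
  if (nrow(k4)) keep <- keep & !overlaps_any(heavy, k4)
  cand <- heavy[keep]
  if (!nrow(cand)) return(empty)
  lumrs <- as.data.table(lumrs)
  hits <- interval_hits(cand, lumrs)
  if (!nrow(hits)) return(empty)
  supp <- hits[, .(lumr_ids = paste(lumrs$lumr_id[s_idx], collapse = ",")), by = q_idx]
  out <- cand[supp$q_idx, .(chrom, start, end, source_peak_id = peak_id)]
  out[, lumr_ids := supp$lumr_ids]
  setorder(out, chrom, start)
  out[, element_id := sprintf("de_%d", .I)]
  setcolorder(out, c("element_id", "chrom", "start", "end",
                     "source_peak_id", "lumr_ids"))
  out[]
}

#' Signal profile matrix around region centers
#'
#' Extracts per-region vectors of binned coverage centered on the TSS (for
#' stranded regions) or the interval midpoint, over +/- `flank` bp at `bin`
#' bp resolution. Minus-strand regions are flipped so that upstream is
#' always on the left. Bins falling off the chromosome are NA, not zero.
#'
#' @param regions data.table with `chrom`, `start`, `end` and optionally
#'   `strand` and `tss`; profile centers use `tss` when present.
#' @param coverage_track named list (per chromosome) of nonnegative numeric
#'   vectors, one value per `bin`-bp genomic bin.
#' @param flank half-width of the profiled window in bp; must be a multiple
#'   of `bin`.
#' @param bin bin width in bp of the coverage track (default 50).
#' @return numeric matrix: rows = regions, columns = offsets from -flank to
#'   +flank - bin; row names from `region_id`/`gene_id` when available.
#' @export
signal_profile <- function(regions, coverage_track, flank = 3000L, bin = 50L) {
  if (flank %% bin != 0) stop("signal_profile: flank must be a multiple of bin")
  regions <- as.data.table(regions)
  nb <- 2L * (flank %/% bin)
  offsets <- seq(-flank, flank - bin, by = bin)
  out <- matrix(NA_real_, nrow = nrow(regions), ncol = nb,
                dimnames = list(NULL, offsets))
  if ("region_id" %in% names(regions)) rownames(out) <- regions$region_id
  else if ("gene_id" %in% names(regions)) rownames(out) <- regions$gene_id
  for (i in seq_len(nrow(regions))) {
    chrom <- as.character(regions$chrom[i])
    track <- coverage_track[[chrom]]
    if (is.null(track)) next
    center <- if ("tss" %in% names(regions) && !is.na(regions$tss[i])) regions$tss[i]
              else interval_mid(regions$start[i], regions$end[i])
    cbin <- center %/% bin
    idx <- cbin + (-(flank %/% bin):(flank %/% bin - 1L))  # genomic bin indices, 0-based
    ok <- idx >= 0L & idx < length(track)
    vals <- rep(NA_real_, nb)
    vals[ok] <- track[idx[ok] + 1L]
    if ("strand" %in% names(regions) && !is.na(regions$strand[i]) &&
        regions$strand[i] == "-") {
      vals <- rev(vals)
    }
    out[i, ] <- vals
  }
  out
}

#' Cluster TSS chromatin states by k-means
#'
#' Concatenates per-mark signal profile matrices row-wise (same genes in the
#' same order) and partitions genes into `k` chromatin states with k-means
#' (k-means++-style multiple restarts via `nstart`). Cluster ids are
#' relabeled in order of decreasing cluster size, so label 1 is always the
#' largest state.
#'
#' @param profiles_by_mark named list of matrices from [signal_profile()],
#'   equal row counts; NA cells are replaced by 0 before clustering.
#' @param k number of states (default 15).
#' @param seed RNG seed for reproducible clustering.
#' @param nstart random restarts (default 10, best inertia kept).
#' @return integer vector of cluster labels (1..k), named by row names of the
#'   first matrix.
#' @export
cluster_tss_states <- function(profiles_by_mark, k = 15L, seed = 1L, nstart = 10L) {
  stopifnot(is.list(profiles_by_mark), length(profiles_by_mark) >= 1)
  nr <- vapply(profiles_by_mark, nrow, integer(1))
  if (length(unique(nr)) != 1) stop("cluster_tss_states: matrices must have equal row counts")
  X <- do.call(cbind, profiles_by_mark)
  X[is.na(X)] <- 0
  if (k > nrow(X)) stop("cluster_tss_states: k exceeds number of genes")
  if (k < 1) stop("cluster_tss_states: k must be >= 1")
  labels <- if (k == 1L) rep(1L, nrow(X)) else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    km <- kmeans(X, centers = k, nstart = nstart, iter.max = 100)
    ## relabel by descending cluster size, ties broken by original label
    sizes <- tabulate(km$cluster, nbins = k)
    remap <- integer(k)
    remap[order(-sizes, seq_len(k))] <- seq_len(k)
    remap[km$cluster]
  }
  names(labels) <- rownames(profiles_by_mark[[1]])
  labels
}

## save/restore the global RNG state so seeded helpers do not perturb the
## caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
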