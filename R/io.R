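## Readers and writers for the standard formats the pipeline touches.
## Internal convention: 0-based half-open coordinates everywhere; GFF3
## conversion on read/write is the only coordinate shift in the package.

#' Read gene models from GFF3
#'
#' Imports `gene` features from a GFF3 file and converts them to the internal
#' 0-based half-open convention. The transcription start site (TSS) is
#' derived from the strand: `start` for `+` genes, `end - 1` for `-` genes.
#'
#' @param path GFF3 file.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return data.table with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop(sprintf("malformed GFF3 '%s': %s", path, conditionMessage(e)))
  )
  gr <- gr[as.character(gr$type) == feature_type]
  if (!length(gr)) {
    return(data.table(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), tss = integer()))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("unstranded gene feature in GFF3; strand required")
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  if (any(is.na(ids))) stop("GFF3 gene feature without ID attribute")
  out <- data.table(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.integer(GenomicRanges::start(gr)) - 1L,  # 1-based -> 0-based
    end = as.integer(GenomicRanges::end(gr)),
    strand = strand
  )
  out[, tss := ifelse(strand == "+", start, end - 1L)]
  validate_intervals(out, "gene models")
  setorder(out, chrom, start)
  out[]
}

#' Write gene models to GFF3
#'
#' @param genes data.table as returned by [read_gff3()].
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  genes <- validate_intervals(genes, "gene models")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read peaks from a BED file
#'
#' BED3 or BED5+; a missing score column yields intensity 0.
#'
#' @param path BED file.
#' @param mark ChIP/MNase mark label attached to every peak (e.g.
#'   `"H3K4me3"`, `"MNase_heavy"`).
#' @return data.table with `peak_id`, `chrom`, `start`, `end`, `intensity`,
#'   `mark`.
#' @export
read_bed <- function(path, mark = NA_character_) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop(sprintf("malformed BED '%s': %s", path, conditionMessage(e)))
  )
  n <- length(gr)
  ids <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name)
         else sprintf("peak_%d", seq_len(n))
  sc <- if (!is.null(gr$score)) as.numeric(gr$score) else rep(0, n)
  sc[is.na(sc)] <- 0
  if (any(sc < 0)) stop("negative peak intensity in BED file")
  out <- data.table(
    peak_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.integer(GenomicRanges::start(gr)) - 1L,
    end = as.integer(GenomicRanges::end(gr)),
    intensity = sc,
    mark = mark
  )
  validate_intervals(out, "peaks")
  out[]
}

#' Write peaks to BED5
#'
#' @param peaks data.table as returned by [read_bed()].
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  peaks <- validate_intervals(peaks, "peaks")
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  gr$name <- peaks$peak_id
  gr$score <- peaks$intensity
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

## Canonicalize anchor order: anchor A <= anchor B by (chrom, start), with
## lexicographic chromosome tie-break.
canonicalize_pairs <- function(x) {
  x <- as.data.table(x)
  if (!nrow(x)) return(x)
  swap <- (as.character(x$chromB) < as.character(x$chromA)) |
    (as.character(x$chromA) == as.character(x$chromB) & x$startB < x$startA)
  if (any(swap)) {
    tmp <- x[swap, .(chromA, startA, endA)]
    x[swap, `:=`(chromA = chromB, startA = startB, endA = endB)]
    x[swap, `:=`(chromB = tmp$chromA, startB = tmp$startA, endB = tmp$endA)]
  }
  x[]
}

#' Read paired-end tags or loops from BEDPE
#'
#' Anchors are normalized to canonical order (anchor A before anchor B by
#' chromosome then start). A missing 7th column defaults the count to 1.
#' Records whose two anchors overlap on the same chromosome are flagged
#' (`flagged = TRUE`), never dropped.
#'
#' @param path BEDPE file (6 columns minimum; col 7 = count, col 8 = source,
#'   col 9 = peak support, when present).
#' @return data.table with `chromA`, `startA`, `endA`, `chromB`, `startB`,
#'   `endB`, `count`, `flagged` and optional `source`, `peak_support`.
#' @export
read_bedpe <- function(path) {
  x <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(x) < 6) stop(sprintf("BEDPE '%s': need at least 6 columns", path))
  if (anyNA(x[[6]])) stop(sprintf("BEDPE '%s': record with fewer than 6 fields", path))
  nm <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  setnames(x, seq_len(6), nm)
  x[, `:=`(chromA = as.character(chromA), chromB = as.character(chromB),
           startA = as.integer(startA), endA = as.integer(endA),
           startB = as.integer(startB), endB = as.integer(endB))]
  if (any(x$endA <= x$startA) || any(x$endB <= x$startB)) {
    stop(sprintf("BEDPE '%s': interval with end <= start", path))
  }
  ncol0 <- ncol(x)
  cnt <- if (ncol0 >= 7) as.integer(x[[7]]) else rep(1L, nrow(x))
  cnt[is.na(cnt)] <- 1L
  src <- if (ncol0 >= 8) as.character(x[[8]]) else rep(NA_character_, nrow(x))
  sup <- if (ncol0 >= 9) as.character(x[[9]]) else rep(NA_character_, nrow(x))
  x <- x[, .(chromA, startA, endA, chromB, startB, endB)]
  x[, `:=`(count = cnt, source = src, peak_support = sup)]
  x <- canonicalize_pairs(x)
  x[, flagged := chromA == chromB & startB < endA & startA < endB]
  setorder(x, chromA, startA, chromB, startB)
  x[]
}

#' Write paired-end tags or loops to BEDPE
#'
#' @param pairs data.table in the layout returned by [read_bedpe()].
#' @param path output file.
#' @export
write_bedpe <- function(pairs, path) {
  pairs <- as.data.table(pairs)
  cols <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  stopifnot(all(cols %in% names(pairs)))
  out <- pairs[, ..cols]
  out[, count := if ("count" %in% names(pairs)) pairs$count
                 else if ("pet_count" %in% names(pairs)) pairs$pet_count else 1L]
  if ("source" %in% names(pairs)) out[, source := pairs$source]
  if ("peak_support" %in% names(pairs)) out[, peak_support := pairs$peak_support]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read per-cytosine methylation calls
#'
#' Tab-separated table with columns `chrom`, `pos` (0-based), `context`
#' (CG/CHG/CHH), `n_meth`, `n_total`.
#'
#' @param path TSV file with header.
#' @return data.table of methylation calls.
#' @export
read_methylation_table <- function(path) {
  x <- fread(path, header = TRUE, sep = "\t")
  req <- c("chrom", "pos", "context", "n_meth", "n_total")
  if (!all(req %in% names(x))) {
    stop(sprintf("methylation table '%s': need columns %s", path, paste(req, collapse = ", ")))
  }
  x <- x[, .(chrom = as.character(chrom), pos = as.integer(pos),
             context = as.character(context),
             n_meth = as.integer(n_meth), n_total = as.integer(n_total))]
  if (any(x$pos < 0)) stop("methylation table: pos < 0")
  if (any(!x$context %in% c("CG", "CHG", "CHH"))) stop("methylation table: unknown context")
  if (any(x$n_total < 1)) stop("methylation table: n_total < 1")
  if (any(x$n_meth > x$n_total) || any(x$n_meth < 0)) {
    stop("methylation table: n_meth outside [0, n_total]")
  }
  setorder(x, chrom, pos)
  x[]
}

#' Write per-cytosine methylation calls
#' @param calls data.table as from [read_methylation_table()].
#' @param path output file.
#' @export
write_methylation_table <- function(calls, path) {
  fwrite(as.data.table(calls)[, .(chrom, pos, context, n_meth, n_total)],
         path, sep = "\t")
  invisible(path)
}

#' Read a genes x tissues FPKM matrix
#'
#' Tab-separated, header row of tissue ids, first column gene ids.
#'
#' @param path TSV file.
#' @return numeric matrix, rownames = gene ids, colnames = tissue ids.
#' @export
read_expression_matrix <- function(path) {
  x <- fread(path, header = TRUE, sep = "\t")
  gid <- as.character(x[[1]])
  if (anyDuplicated(gid)) stop("expression matrix: duplicate gene ids")
  if (anyDuplicated(names(x)[-1])) stop("expression matrix: duplicate tissue ids")
  m <- as.matrix(x[, -1, with = FALSE])
  if (!is.numeric(m)) stop("expression matrix: non-numeric FPKM value")
  if (anyNA(m)) stop("expression matrix: missing FPKM value")
  if (any(m < 0)) stop("expression matrix: negative FPKM value")
  rownames(m) <- gid
  m
}

#' Write a genes x tissues FPKM matrix
#' @param mat numeric matrix with gene rownames and tissue colnames.
#' @param path output file.
#' @export
write_expression_matrix <- function(mat, path) {
  dt <- data.table(gene_id = rownames(mat))
  dt <- cbind(dt, as.data.table(mat))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read an eQTL or GWAS association table
#'
#' Tab-separated with header: `snp_chrom`, `snp_pos` and, for eQTL tables,
#' `gene_id` and `type` (cis/trans). GWAS tables need only the SNP columns.
#'
#' @param path TSV file.
#' @param require_gene require the `gene_id` column (TRUE for eQTL tables).
#' @return data.table of associations.
#' @export
read_association_table <- function(path, require_gene = TRUE) {
  x <- fread(path, header = TRUE, sep = "\t")
  req <- c("snp_chrom", "snp_pos")
  if (require_gene) req <- c(req, "gene_id")
  if (!all(req %in% names(x))) {
    stop(sprintf("association table '%s': need columns %s", path, paste(req, collapse = ", ")))
  }
  x[, `:=`(snp_chrom = as.character(snp_chrom), snp_pos = as.integer(snp_pos))]
  if (any(x$snp_pos < 0)) stop("association table: snp_pos < 0")
  if (require_gene) {
    x[, gene_id := as.character(gene_id)]
    if (any(is.na(x$gene_id) | !nzchar(x$gene_id))) {
      stop("association table: missing gene id")
    }
    if (!"type" %in% names(x)) x[, type := NA_character_]
    x[, type := as.character(type)]
  }
  x[]
}

#' Write an association table
#' @param assoc data.table as from [read_association_table()].
#' @param path output file.
#' @export
write_association_table <- function(assoc, path) {
  fwrite(as.data.table(assoc), path, sep = "\t")
  invisible(path)
}
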