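## Internal interval machinery. All intervals are data.tables with at least
## chrom / start / end columns, 0-based half-open. Overlap queries are
## delegated to data.table::foverlaps on closed integer coordinates
## (end - 1), so "overlap" always means >= 1 shared base unless a larger
## min_overlap is requested.

#' Validate an interval table
#'
#' Checks the basic coordinate invariants shared by every positional table in
#' the package: nonempty chromosome names, `start >= 0`, `end > start`.
#'
#' @param x data.table with `chrom`, `start`, `end` columns (0-based
#'   half-open).
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval table") {
  stopifnot(is.data.frame(x))
  x <- as.data.table(x)
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(x)) {
    if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
      stop(sprintf("%s: empty chromosome name", what))
    }
    if (any(x$start < 0)) stop(sprintf("%s: start < 0", what))
    if (any(x$end <= x$start)) stop(sprintf("%s: end <= start", what))
  }
  invisible(x)
}

## All pairwise overlaps of >= min_overlap bp between two interval tables.
## Returns data.table(q_idx, s_idx, overlap) of row indices into q and s.
interval_hits <- function(q, s, min_overlap = 1L) {
  q <- as.data.table(q)
  s <- as.data.table(s)
  if (!nrow(q) || !nrow(s)) {
    return(data.table(q_idx = integer(), s_idx = integer(), overlap = integer()))
  }
  qq <- data.table(chrom = as.character(q$chrom),
                   start = as.integer(q$start),
                   end = as.integer(q$end) - 1L,
                   q_idx = seq_len(nrow(q)))
  ss <- data.table(chrom = as.character(s$chrom),
                   start = as.integer(s$start),
                   end = as.integer(s$end) - 1L,
                   s_idx = seq_len(nrow(s)))
  setkey(ss, chrom, start, end)
  ov <- foverlaps(qq, ss, by.x = c("chrom", "start", "end"), nomatch = NULL)
  ## foverlaps keeps subject coords in start/end and query coords in i.start/i.end
  ov[, overlap := pmin(end, i.end) - pmax(start, i.start) + 1L]
  ov <- ov[overlap >= min_overlap]
  out <- ov[, .(q_idx, s_idx, overlap)]
  setorder(out, q_idx, s_idx)
  out[]
}

## Logical: does each row of q overlap any row of s by >= min_overlap bp?
overlaps_any <- function(q, s, min_overlap = 1L) {
  res <- rep(FALSE, nrow(q))
  hits <- interval_hits(q, s, min_overlap)
  res[unique(hits$q_idx)] <- TRUE
  res
}

## Merge overlapping-or-touching intervals within each chromosome.
## touching = TRUE also merges bookended intervals ([a,b) + [b,c)).
merge_intervals <- function(x, touching = TRUE) {
  x <- as.data.table(x)
  if (!nrow(x)) return(data.table(chrom = character(), start = integer(), end = integer()))
  x <- x[, .(chrom = as.character(chrom), start = as.integer(start), end = as.integer(end))]
  setorder(x, chrom, start, end)
  slack <- if (touching) 0L else -1L
  x[, grp := cumsum(c(1L, as.integer(start[-1] > cummax(end[-.N]) + slack))), by = chrom]
  out <- x[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  out[, grp := NULL]
  setorder(out, chrom, start)
  out[]
}

## Interval midpoints (floor of the center of a half-open interval).
interval_mid <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}
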