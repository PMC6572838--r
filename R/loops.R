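## PET categorization, loop calling with tag-count and peak-support filters,
## loop-set merging and distance-normalized contact matrices.

#' Categorize paired-end tags
#'
#' Each PET is categorized by the genomic span between its two tags:
#' different chromosomes give `interchromosomal`; same chromosome with
#' midpoint span below `self_span_threshold` gives `self_ligation`;
#' otherwise `inter_ligation`. The categorization is a total partition.
#'
#' @param pets data.table in [read_bedpe()] layout (canonical anchor order).
#' @param self_span_threshold span in bp below which a same-chromosome PET is
#'   treated as a self-ligation product (default 8000).
#' @return input with added `span` (NA for interchromosomal) and `category`
#'   columns.
#' @export
categorize_pets <- function(pets, self_span_threshold = 8000L) {
  if (self_span_threshold < 0) stop("categorize_pets: negative span threshold")
  pets <- canonicalize_pairs(as.data.table(pets))
  if (!nrow(pets)) {
    pets[, `:=`(span = integer(), category = character())]
    return(pets[])
  }
  midA <- interval_mid(pets$startA, pets$endA)
  midB <- interval_mid(pets$startB, pets$endB)
  same <- pets$chromA == pets$chromB
  pets[, span := ifelse(same, abs(midB - midA), NA_integer_)]
  pets[, category := fifelse(!same, "interchromosomal",
                      fifelse(span < self_span_threshold, "self_ligation",
                              "inter_ligation"))]
  pets[]
}

## Build anchor regions from tags: extend each tag by `ext` bp on both sides
## and merge overlapping extensions per chromosome. Returns the merged
## anchor table plus the anchor id each tag maps to.
build_anchors <- function(tags, ext) {
  tags <- as.data.table(tags)
  extd <- tags[, .(chrom, start = pmax(0L, start - as.integer(ext)),
                   end = end + as.integer(ext))]
  anchors <- merge_intervals(extd, touching = FALSE)
  anchors[, anchor_id := .I]
  hits <- interval_hits(extd, anchors)
  ## every extended tag falls in exactly one merged anchor
  tag_anchor <- hits[order(q_idx)]$s_idx
  list(anchors = anchors, tag_anchor = tag_anchor)
}

#' Call chromatin loops from inter-ligation PETs
#'
#' PET tags are extended by `anchor_extension` bp on each side; overlapping
#' extended tags are merged into anchor regions; PETs are grouped by their
#' (anchor A, anchor B) pair. A candidate is emitted as a loop only if its
#' paired-end tag count is at least `min_pet_count` and at least one of the
#' two anchors overlaps a ChIP peak of the matching mark; peak support is
#' recorded as `"both"` or `"one"`.
#'
#' @param inter_pets inter-ligation PETs ([read_bedpe()] layout).
#' @param peaks ChIP peaks of the mark the ChIA-PET library was made with.
#' @param min_pet_count minimum supporting PET count (default 3).
#' @param anchor_extension bp added to each side of a tag before merging
#'   (default 500; reproduces ~1-kb anchors).
#' @param source mark label stored on emitted loops.
#' @return data.table of loops: `loop_id`, anchor coordinates, `pet_count`,
#'   `source`, `peak_support`, `span`.
#' @export
call_loops <- function(inter_pets, peaks, min_pet_count = 3L,
                       anchor_extension = 500L, source = "H3K4me3") {
  if (min_pet_count < 1) stop("call_loops: min_pet_count must be >= 1")
  pets <- canonicalize_pairs(as.data.table(inter_pets))
  empty <- data.table(loop_id = character(), chromA = character(),
                      startA = integer(), endA = integer(),
                      chromB = character(), startB = integer(), endB = integer(),
                      pet_count = integer(), source = character(),
                      peak_support = character(), span = integer())
  if (!nrow(pets)) return(empty)
  tagsA <- pets[, .(chrom = chromA, start = startA, end = endA)]
  tagsB <- pets[, .(chrom = chromB, start = startB, end = endB)]
  ab <- build_anchors(rbind(tagsA, tagsB), anchor_extension)
  n <- nrow(pets)
  aA <- ab$tag_anchor[seq_len(n)]
  aB <- ab$tag_anchor[n + seq_len(n)]
  ## canonical anchor-pair key (self-pairs excluded: both tags in one anchor)
  lo <- pmin(aA, aB); hi <- pmax(aA, aB)
  cand <- data.table(a1 = lo, a2 = hi)[lo != hi, .N, by = .(a1, a2)]
  if (!nrow(cand)) return(empty)
  setnames(cand, "N", "pet_count")
  cand <- cand[pet_count >= min_pet_count]
  if (!nrow(cand)) return(empty)
  anch <- ab$anchors
  has_peak <- overlaps_any(anch, as.data.table(peaks))
  cand[, peak_support := c("none", "one", "both")[
    1L + as.integer(has_peak[a1]) + as.integer(has_peak[a2])]]
  cand <- cand[peak_support != "none"]
  if (!nrow(cand)) return(empty)
  out <- data.table(
    chromA = anch$chrom[cand$a1], startA = anch$start[cand$a1], endA = anch$end[cand$a1],
    chromB = anch$chrom[cand$a2], startB = anch$start[cand$a2], endB = anch$end[cand$a2],
    pet_count = cand$pet_count, source = source, peak_support = cand$peak_support
  )
  out <- canonicalize_pairs(out)
  out[, span := ifelse(chromA == chromB,
                       abs(interval_mid(startB, endB) - interval_mid(startA, endA)),
                       NA_integer_)]
  setorder(out, chromA, startA, chromB, startB)
  out[, loop_id := sprintf("loop_%d", .I)]
  setcolorder(out, c("loop_id", "chromA", "startA", "endA",
                     "chromB", "startB", "endB", "pet_count",
                     "source", "peak_support", "span"))
  out[]
}

#' Intra- versus inter-chromosomal loop counts
#'
#' @param loops loop table.
#' @return data.table with `locality`, `n`, `fraction`.
#' @export
classify_loop_locality <- function(loops) {
  loops <- as.data.table(loops)
  intra <- sum(loops$chromA == loops$chromB)
  inter <- nrow(loops) - intra
  data.table(locality = c("intra", "inter"),
             n = c(intra, inter),
             fraction = if (nrow(loops)) c(intra, inter) / nrow(loops) else c(NA_real_, NA_real_))
}

#' Merge two loop sets
#'
#' Loops from the two sets whose anchors reciprocally overlap (anchor A with
#' anchor A and anchor B with anchor B, >= 1 bp each) are unified into one
#' loop with summed PET counts and source `"merged"`; all other loops pass
#' through unchanged.
#'
#' @param setA,setB loop tables ([call_loops()] layout).
#' @return merged loop table.
#' @export
merge_loop_sets <- function(setA, setB) {
  a <- as.data.table(setA); b <- as.data.table(setB)
  if (!nrow(a)) return(copy(b))
  if (!nrow(b)) return(copy(a))
  hitsA <- interval_hits(a[, .(chrom = chromA, start = startA, end = endA)],
                         b[, .(chrom = chromA, start = startA, end = endA)])
  hitsB <- interval_hits(a[, .(chrom = chromB, start = startB, end = endB)],
                         b[, .(chrom = chromB, start = startB, end = endB)])
  both <- merge(hitsA[, .(q_idx, s_idx)], hitsB[, .(q_idx, s_idx)],
                by = c("q_idx", "s_idx"))
  ## greedy 1:1 pairing in table order
  both <- both[order(q_idx, s_idx)]
  usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
  pairs <- list()
  for (r in seq_len(nrow(both))) {
    i <- both$q_idx[r]; j <- both$s_idx[r]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  merged <- if (length(pairs)) {
    ij <- do.call(rbind, pairs)
    m <- copy(a[ij[, 1]])
    m[, pet_count := pet_count + b$pet_count[ij[, 2]]]
    m[, source := "merged"]
    m
  } else NULL
  out <- rbind(merged, a[!usedA], b[!usedB], fill = TRUE)
  out <- canonicalize_pairs(out)
  setorder(out, chromA, startA, chromB, startB)
  out[, loop_id := sprintf("loop_%d", .I)]
  out[]
}

#' Contact frequency matrix from PETs
#'
#' Bins one chromosome at the given resolution and counts PET tag pairs per
#' bin pair. The matrix is symmetric.
#'
#' @param pets PET table; only intra-chromosomal PETs of `chrom` are used.
#' @param chrom chromosome to build the matrix for.
#' @param chrom_length chromosome length in bp.
#' @param resolution bin size in bp (conventionally 1 Mb, 50 kb or 5 kb).
#' @return list with `observed` (symmetric count matrix), `resolution`,
#'   `chrom`.
#' @export
contact_matrix <- function(pets, chrom, chrom_length, resolution = 50000L) {
  if (resolution <= 0) stop("contact_matrix: resolution must be positive")
  nb <- as.integer(ceiling(chrom_length / resolution))
  obs <- matrix(0, nb, nb)
  pets <- as.data.table(pets)
  pets <- pets[chromA == chrom & chromB == chrom]
  if (nrow(pets)) {
    bi <- pmin(nb - 1L, interval_mid(pets$startA, pets$endA) %/% as.integer(resolution)) + 1L
    bj <- pmin(nb - 1L, interval_mid(pets$startB, pets$endB) %/% as.integer(resolution)) + 1L
    for (r in seq_along(bi)) {
      obs[bi[r], bj[r]] <- obs[bi[r], bj[r]] + 1
      if (bi[r] != bj[r]) obs[bj[r], bi[r]] <- obs[bj[r], bi[r]] + 1
    }
  }
  list(observed = obs, resolution = as.integer(resolution), chrom = chrom)
}

#' Distance-normalize a contact matrix
#'
#' Observed/expected normalization: each cell is divided by the mean
#' observed count over all bin pairs at the same distance `|i - j|`.
#' Distances with zero total mass are left at 0.
#'
#' @param cm list from [contact_matrix()].
#' @return same list with an added `normalized` matrix.
#' @export
distance_normalize <- function(cm) {
  obs <- cm$observed
  nb <- nrow(obs)
  norm <- matrix(0, nb, nb)
  d <- abs(row(obs) - col(obs))
  for (dd in 0:(nb - 1)) {
    sel <- d == dd
    mu <- mean(obs[sel])
    if (mu > 0) norm[sel] <- obs[sel] / mu
  }
  cm$normalized <- norm
  cm
}
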