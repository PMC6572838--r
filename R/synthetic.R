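## Seed-reproducible synthetic input bundles with a planted ground-truth
## manifest. The generator emulates the statistical structure the downstream
## analyses assume: non-overlapping genes, ~1-kb loop anchors at promoters,
## hypomethylated blocks hosting accessible distal elements, PETs expanded
## from planted loops plus uniform noise PETs, a shared-latent-factor
## co-expression effect for looped gene pairs, and eQTL/GWAS tables with a
## configured fraction of loop-linked records.

#' Synthetic bundle configuration
#'
#' Returns a validated configuration list for [generate_bundle()]. Defaults
#' describe the reference validation genome: one 10-Mb chromosome, 300
#' genes, 50 planted loops spanning 10-100 kb, 20 hypomethylated blocks,
#' 1000 noise PETs, 79 expression tissues and a planted looped-pair
#' co-expression of rho = 0.6.
#'
#' @param ... overrides of any default field.
#' @return named list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_chromosomes = 1L,
    chromosome_length = 10e6,
    n_genes = 300L,
    gene_length_range = c(2000L, 5000L),
    gene_min_gap = 6000L,
    promoter_upstream = 2000L,
    promoter_downstream = 1500L,
    n_planted_loops = 50L,
    loop_span_range = c(10000L, 100000L),
    ppi_fraction = 0.5,
    pdi_fraction = 0.3,
    pdi_multi_fraction = 1 / 3,
    anchor_width_range = c(800L, 1200L),
    pet_per_loop_range = c(3L, 8L),
    tag_width = 100L,
    n_noise_pets = 1000L,
    n_planted_lumrs = 20L,
    n_extra_distal = 5L,
    lumr_width_bins = c(5L, 12L),
    background_methylation = c(CG = 0.85, CHG = 0.70, CHH = 0.05),
    lumr_methylation = c(CG = 0.05, CHG = 0.02, CHH = 0.01),
    meth_bin_size = 200L,
    meth_site_spacing = 40L,
    meth_coverage_mean = 20,
    n_tissues = 79L,
    coexpression_rho = 0.6,
    background_rho = 0,
    expression_sigma = 1,
    h3k4me3_gene_fraction = 0.7,
    rnapii_gene_fraction = 0.6,
    n_decoy_heavy_per_class = 10L,
    n_eqtls = 100L,
    eqtl_loop_link_fraction = 0.5,
    n_gwas_snps = 20L,
    gwas_window = 200000L,
    gwas_element_link_fraction = 0.5,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop(sprintf("synth_config: unknown field(s): %s",
                                    paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  counts <- c("n_chromosomes", "n_genes", "n_planted_loops", "n_planted_lumrs",
              "n_extra_distal", "n_noise_pets", "n_tissues", "n_eqtls",
              "n_gwas_snps", "n_decoy_heavy_per_class")
  for (f in counts) if (cfg[[f]] < 0) stop(sprintf("synth_config: %s must be >= 0", f))
  fracs <- c("ppi_fraction", "pdi_fraction", "pdi_multi_fraction",
             "coexpression_rho", "background_rho", "h3k4me3_gene_fraction",
             "rnapii_gene_fraction", "eqtl_loop_link_fraction",
             "gwas_element_link_fraction")
  for (f in fracs) if (cfg[[f]] < 0 || cfg[[f]] > 1) {
    stop(sprintf("synth_config: %s must be in [0, 1]", f))
  }
  if (cfg$ppi_fraction + cfg$pdi_fraction > 1) {
    stop("synth_config: ppi_fraction + pdi_fraction must be <= 1")
  }
  if (cfg$loop_span_range[1] <= 0 || cfg$loop_span_range[2] >= cfg$chromosome_length) {
    stop("synth_config: loop_span_range must lie within (0, chromosome_length)")
  }
  structure(cfg, class = "synth_config")
}

## place n non-overlapping genes on one chromosome with a minimum gap,
## via stick-breaking over the free slack (deterministic given the RNG)
place_genes <- function(n, chrom_len, len_range, min_gap) {
  lens <- as.integer(round(runif(n, len_range[1], len_range[2])))
  need <- sum(lens) + (n + 1) * min_gap
  if (need > chrom_len) {
    stop(sprintf("generate_bundle: %d non-overlapping genes do not fit in %g bp", n, chrom_len))
  }
  slack <- chrom_len - need
  cuts <- sort(runif(n, 0, slack))
  starts <- as.integer(floor(min_gap * seq_len(n) + c(0, cumsum(lens))[seq_len(n)] + cuts))
  data.table(start = starts, end = starts + lens)
}

#' Expand a planted loop into supporting PETs
#'
#' Emits `n_pets` paired-end tags whose two tags fall inside the loop's two
#' anchors: tag centers are the anchor midpoints jittered uniformly by up to
#' `anchor_jitter` bp. With zero jitter all PETs are identical and sit at
#' the anchor midpoints.
#'
#' @param loop single-row data.table with `chromA..endB` anchor coordinates.
#' @param n_pets number of PETs (>= 1).
#' @param anchor_jitter maximum absolute jitter of a tag center; defaults to
#'   the largest value keeping tags inside their anchors. Must not exceed
#'   that bound.
#' @param tag_width tag width in bp (default 100).
#' @return data.table of PETs in [read_bedpe()] layout.
#' @export
expand_loop_to_pets <- function(loop, n_pets, anchor_jitter = NULL, tag_width = 100L) {
  if (n_pets < 1) stop("expand_loop_to_pets: n_pets must be >= 1")
  loop <- as.data.table(loop)
  stopifnot(nrow(loop) == 1)
  half <- tag_width %/% 2
  maxjA <- (loop$endA - loop$startA - tag_width) / 2
  maxjB <- (loop$endB - loop$startB - tag_width) / 2
  maxj <- max(0, floor(min(maxjA, maxjB)))
  if (is.null(anchor_jitter)) anchor_jitter <- maxj
  if (anchor_jitter > min(maxjA, maxjB)) {
    stop("expand_loop_to_pets: jitter larger than anchor width allows")
  }
  midA <- interval_mid(loop$startA, loop$endA)
  midB <- interval_mid(loop$startB, loop$endB)
  jA <- if (anchor_jitter > 0) as.integer(round(runif(n_pets, -anchor_jitter, anchor_jitter))) else rep(0L, n_pets)
  jB <- if (anchor_jitter > 0) as.integer(round(runif(n_pets, -anchor_jitter, anchor_jitter))) else rep(0L, n_pets)
  out <- data.table(
    chromA = loop$chromA, startA = midA + jA - half, endA = midA + jA - half + tag_width,
    chromB = loop$chromB, startB = midB + jB - half, endB = midB + jB - half + tag_width,
    count = 1L, source = NA_character_, peak_support = NA_character_
  )
  canonicalize_pairs(out)
}

## sample a clear genomic interval: not overlapping `occupied` (expanded by
## margin). Returns c(start, end) or NULL after max_attempts.
sample_clear_interval <- function(chrom, width, chrom_len, occupied, margin,
                                  max_attempts = 500L) {
  for (i in seq_len(max_attempts)) {
    s <- as.integer(floor(runif(1, margin, chrom_len - width - margin)))
    cand <- data.table(chrom = chrom, start = s - margin, end = s + width + margin)
    if (!nrow(occupied) || !overlaps_any(cand, occupied)[1]) return(c(s, s + width))
  }
  NULL
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' Produces every input the downstream pipeline consumes, plus a manifest of
#' the planted objects. Identical `(config, seed)` gives a byte-identical
#' bundle when written with [write_bundle()].
#'
#' @param config list from [synth_config()].
#' @return list with `config`, `chrom_lengths`, `genes`, `peaks` (named list
#'   of data.tables per mark), `methylation`, `pets`, `expression`,
#'   `eqtls`, `gwas_snps`, and `manifest` (planted loops, LUMRs, distal
#'   elements, co-expressed pairs, linked eQTLs/GWAS SNPs).
#' @export
generate_bundle <- function(config = synth_config()) {
  cfg <- config
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  chrom_lengths <- setNames(rep(cfg$chromosome_length, cfg$n_chromosomes), chroms)

  ## ---- genes --------------------------------------------------------------
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
  genes <- rbindlist(lapply(seq_along(chroms), function(ci) {
    g <- place_genes(per_chrom[ci], cfg$chromosome_length,
                     cfg$gene_length_range, cfg$gene_min_gap)
    g[, chrom := chroms[ci]]
    g
  }))
  genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  setorder(genes, chrom, start)
  genes[, gene_id := sprintf("gene_%04d", .I)]
  genes[, tss := ifelse(strand == "+", start, end - 1L)]
  setcolorder(genes, c("gene_id", "chrom", "start", "end", "strand", "tss"))
  promoters <- call_promoter_regions(genes, cfg$promoter_upstream,
                                     cfg$promoter_downstream, chrom_lengths)

  ## registry of planted non-gene features, to keep them separable
  occupied <- genes[, .(chrom, start = pmax(0L, start - 2500L), end = end + 2500L)]
  add_occupied <- function(chrom, start, end) {
    occupied <<- rbind(occupied, data.table(chrom = chrom, start = as.integer(start),
                                            end = as.integer(end)))
  }

  ## ---- loop frame ---------------------------------------------------------
  n_ppi <- round(cfg$n_planted_loops * cfg$ppi_fraction)
  n_pdi <- round(cfg$n_planted_loops * cfg$pdi_fraction)
  n_other <- cfg$n_planted_loops - n_ppi - n_pdi
  span_lo <- cfg$loop_span_range[1]; span_hi <- cfg$loop_span_range[2]
  used_genes <- character(0)
  rand_width <- function(n) as.integer(round(runif(n, cfg$anchor_width_range[1],
                                                   cfg$anchor_width_range[2])))
  anchor_at <- function(center, w) {
    c(as.integer(center - w %/% 2), as.integer(center - w %/% 2 + w))
  }

  ## PPI gene pairs: disjoint genes with TSS distance inside the span range
  ppi_pairs <- list()
  if (n_ppi > 0) {
    ord <- sample(nrow(genes))
    for (i in ord) {
      if (length(ppi_pairs) >= n_ppi) break
      g1 <- genes[i]
      if (g1$gene_id %in% used_genes) next
      cand <- genes[chrom == g1$chrom & !gene_id %in% c(used_genes, g1$gene_id)]
      cand <- cand[abs(tss - g1$tss) >= span_lo & abs(tss - g1$tss) <= span_hi]
      if (!nrow(cand)) next
      g2 <- cand[sample(.N, 1)]
      used_genes <- c(used_genes, g1$gene_id, g2$gene_id)
      ppi_pairs[[length(ppi_pairs) + 1L]] <- c(g1$gene_id, g2$gene_id)
    }
    if (length(ppi_pairs) < n_ppi) {
      stop(sprintf("generate_bundle: only %d of %d PPI gene pairs fit the span range",
                   length(ppi_pairs), n_ppi))
    }
  }

  ## ---- PDI elements and their LUMR blocks ---------------------------------
  bs <- cfg$meth_bin_size
  n_multi_el <- floor(n_pdi * cfg$pdi_multi_fraction / 2)
  n_single_el <- n_pdi - 2L * n_multi_el
  n_elements <- n_multi_el + n_single_el + cfg$n_extra_distal
  if (cfg$n_planted_lumrs < n_elements) {
    stop("generate_bundle: n_planted_lumrs must be >= number of planted distal elements")
  }
  lumr_rows <- list(); element_rows <- list(); pdi_loops <- list()
  place_element_near <- function(tss_pos, chrom) {
    ## element center at a span-range distance from the TSS, inside a
    ## grid-aligned hypomethylated block clear of every other feature
    for (att in seq_len(400L)) {
      d <- as.integer(round(runif(1, span_lo, span_hi)))
      dir <- sample(c(-1L, 1L), 1L)
      center <- tss_pos + dir * d
      we <- as.integer(round(runif(1, 500, 800)))
      nb <- as.integer(round(runif(1, cfg$lumr_width_bins[1], cfg$lumr_width_bins[2])))
      lumr_start <- (as.integer(center - (nb * bs) %/% 2) %/% bs) * bs
      lumr_end <- lumr_start + nb * bs
      if (lumr_start < bs || lumr_end > cfg$chromosome_length - bs) next
      cand <- data.table(chrom = chrom, start = lumr_start - bs, end = lumr_end + bs)
      if (overlaps_any(cand, occupied)[1]) next
      el <- anchor_at(center, we)
      if (el[1] < lumr_start || el[2] > lumr_end) {
        el <- c(lumr_start + (nb * bs - we) %/% 2L, lumr_start + (nb * bs - we) %/% 2L + we)
      }
      return(list(lumr = c(lumr_start, lumr_end), el = el, center = center))
    }
    NULL
  }

  loop_frame <- list()
  add_loop <- function(chrom, cA, wA, cB, wB, label, geneA, geneB, element_id,
                       eqtl_eligible = TRUE) {
    a <- anchor_at(cA, wA); b <- anchor_at(cB, wB)
    loop_frame[[length(loop_frame) + 1L]] <<- data.table(
      chromA = chrom, startA = a[1], endA = a[2],
      chromB = chrom, startB = b[1], endB = b[2],
      label = label, geneA = geneA, geneB = geneB, element_id = element_id,
      eqtl_eligible = eqtl_eligible)
  }
  for (p in ppi_pairs) {
    g1 <- genes[gene_id == p[1]]; g2 <- genes[gene_id == p[2]]
    add_loop(g1$chrom, g1$tss, rand_width(1), g2$tss, rand_width(1),
             "PPI", p[1], p[2], NA_character_)
  }

  el_counter <- 0L
  coexpr_extra <- list()  # multi-element gene pairs sharing a latent factor
  make_pdi <- function(multi) {
    free <- genes[!gene_id %in% used_genes]
    if (!nrow(free)) stop("generate_bundle: no free genes left for PDI loops")
    for (att in seq_len(200L)) {
      g1 <- free[sample(.N, 1)]
      pl <- place_element_near(g1$tss, g1$chrom)
      if (is.null(pl)) next
      g2 <- NULL
      if (multi) {
        cand <- genes[chrom == g1$chrom & !gene_id %in% c(used_genes, g1$gene_id)]
        cand <- cand[abs(tss - pl$center) >= span_lo & abs(tss - pl$center) <= span_hi]
        if (!nrow(cand)) next
        g2 <- cand[sample(.N, 1)]
      }
      el_counter <<- el_counter + 1L
      eid <- sprintf("planted_de_%d", el_counter)
      lumr_rows[[length(lumr_rows) + 1L]] <<- data.table(
        chrom = g1$chrom, start = pl$lumr[1], end = pl$lumr[2], element_id = eid)
      element_rows[[length(element_rows) + 1L]] <<- data.table(
        element_id = eid, chrom = g1$chrom, start = pl$el[1], end = pl$el[2],
        interacting = TRUE)
      add_occupied(g1$chrom, pl$lumr[1] - bs, pl$lumr[2] + bs)
      used_genes <<- c(used_genes, g1$gene_id)
      we <- pl$el[2] - pl$el[1]
      el_mid <- interval_mid(pl$el[1], pl$el[2])
      add_loop(g1$chrom, el_mid, we, g1$tss, rand_width(1),
               "PDI", NA_character_, g1$gene_id, eid)
      if (multi) {
        ## the partner gene stays free of eQTL association, so that it can
        ## later be recovered as an eQTL-interacting gene
        used_genes <<- c(used_genes, g2$gene_id)
        add_loop(g1$chrom, el_mid, we, g2$tss, rand_width(1),
                 "PDI", NA_character_, g2$gene_id, eid, eqtl_eligible = FALSE)
        coexpr_extra[[length(coexpr_extra) + 1L]] <<- c(g1$gene_id, g2$gene_id)
      }
      return(invisible(TRUE))
    }
    stop("generate_bundle: could not place a PDI distal element in clear space")
  }
  if (n_multi_el > 0) for (i in seq_len(n_multi_el)) make_pdi(TRUE)
  if (n_single_el > 0) for (i in seq_len(n_single_el)) make_pdi(FALSE)

  ## non-interacting distal elements (for the GWAS contrast)
  if (cfg$n_extra_distal > 0) for (i in seq_len(cfg$n_extra_distal)) {
    chrom <- sample(chroms, 1)
    nb <- as.integer(round(runif(1, cfg$lumr_width_bins[1], cfg$lumr_width_bins[2])))
    pos <- sample_clear_interval(chrom, nb * bs, chrom_lengths[[chrom]], occupied, bs)
    if (is.null(pos)) stop("generate_bundle: could not place a non-interacting distal element")
    lumr_start <- (pos[1] %/% bs) * bs; lumr_end <- lumr_start + nb * bs
    we <- as.integer(round(runif(1, 500, 800)))
    el_counter <- el_counter + 1L
    eid <- sprintf("planted_de_%d", el_counter)
    es <- lumr_start + (nb * bs - we) %/% 2L
    lumr_rows[[length(lumr_rows) + 1L]] <- data.table(
      chrom = chrom, start = lumr_start, end = lumr_end, element_id = eid)
    element_rows[[length(element_rows) + 1L]] <- data.table(
      element_id = eid, chrom = chrom, start = es, end = es + we, interacting = FALSE)
    add_occupied(chrom, lumr_start - bs, lumr_end + bs)
  }

  ## bare hypomethylated blocks (no element on them)
  n_bare <- cfg$n_planted_lumrs - n_elements
  if (n_bare > 0) for (i in seq_len(n_bare)) {
    chrom <- sample(chroms, 1)
    nb <- as.integer(round(runif(1, cfg$lumr_width_bins[1], cfg$lumr_width_bins[2])))
    pos <- sample_clear_interval(chrom, nb * bs, chrom_lengths[[chrom]], occupied, bs)
    if (is.null(pos)) stop("generate_bundle: could not place a bare LUMR block")
    lumr_start <- (pos[1] %/% bs) * bs
    lumr_rows[[length(lumr_rows) + 1L]] <- data.table(
      chrom = chrom, start = lumr_start, end = lumr_start + nb * bs,
      element_id = NA_character_)
    add_occupied(chrom, lumr_start - bs, lumr_start + nb * bs + bs)
  }

  ## "other" loops: anchors in clear intergenic space, one anchor with a
  ## decoy H3K4me3 peak for the peak-support filter
  decoy_k4 <- list()
  if (n_other > 0) for (i in seq_len(n_other)) {
    placed <- FALSE
    for (att in seq_len(200L)) {
      chrom <- sample(chroms, 1)
      wA <- rand_width(1); wB <- rand_width(1)
      d <- as.integer(round(runif(1, span_lo, span_hi)))
      posA <- sample_clear_interval(chrom, wA, chrom_lengths[[chrom]] - d - wB - 4000,
                                    occupied, 1000L)
      if (is.null(posA)) next
      cB <- posA[1] + wA %/% 2 + d
      b <- anchor_at(cB, wB)
      candB <- data.table(chrom = chrom, start = b[1] - 1000L, end = b[2] + 1000L)
      if (overlaps_any(candB, occupied)[1]) next
      add_occupied(chrom, posA[1] - 1000L, posA[2] + 1000L)
      add_occupied(chrom, b[1] - 1000L, b[2] + 1000L)
      add_loop(chrom, posA[1] + wA %/% 2, wA, cB, wB, "other",
               NA_character_, NA_character_, NA_character_)
      decoy_k4[[length(decoy_k4) + 1L]] <- data.table(
        chrom = chrom, start = posA[1], end = posA[2])
      placed <- TRUE
      break
    }
    if (!placed) stop("generate_bundle: could not place an 'other' loop in clear space")
  }

  loops <- rbindlist(loop_frame)
  loops <- canonicalize_pairs(loops)
  setorder(loops, chromA, startA, chromB, startB)
  loops[, loop_id := sprintf("planted_loop_%d", .I)]
  loops[, n_pets := sample(seq(cfg$pet_per_loop_range[1], cfg$pet_per_loop_range[2]),
                           .N, replace = TRUE)]
  loops[, span := abs(interval_mid(startB, endB) - interval_mid(startA, endA))]

  lumrs <- rbindlist(lumr_rows)
  setorder(lumrs, chrom, start)
  lumrs[, lumr_id := sprintf("planted_lumr_%d", .I)]
  elements <- if (length(element_rows)) rbindlist(element_rows) else
    data.table(element_id = character(), chrom = character(), start = integer(),
               end = integer(), interacting = logical())
  setorder(elements, chrom, start)

  ## ---- PETs ---------------------------------------------------------------
  planted_pets <- rbindlist(lapply(seq_len(nrow(loops)), function(i) {
    expand_loop_to_pets(loops[i], loops$n_pets[i], tag_width = cfg$tag_width)
  }))
  noise_pets <- NULL
  if (cfg$n_noise_pets > 0) {
    n <- cfg$n_noise_pets
    max_span <- min(1e6, 0.3 * cfg$chromosome_length)
    chromA <- sample(chroms, n, replace = TRUE)
    u <- runif(n)
    span <- integer(n)
    self <- u < 0.25
    interchrom <- u > 0.95 & cfg$n_chromosomes >= 2
    inter <- !self & !interchrom
    span[self] <- as.integer(round(exp(runif(sum(self), log(200), log(7900)))))
    span[inter] <- as.integer(round(exp(runif(sum(inter), log(8000), log(max_span)))))
    startA <- as.integer(floor(runif(n, 0, chrom_lengths[chromA] - span - 2 * cfg$tag_width)))
    chromB <- chromA
    chromB[interchrom] <- vapply(chromA[interchrom], function(ch) {
      sample(setdiff(chroms, ch), 1)
    }, character(1))
    startB <- ifelse(interchrom,
                     as.integer(floor(runif(n, 0, chrom_lengths[chromB] - 1000))),
                     startA + span)
    noise_pets <- data.table(
      chromA = chromA, startA = startA, endA = startA + cfg$tag_width,
      chromB = chromB, startB = as.integer(startB),
      endB = as.integer(startB) + cfg$tag_width,
      count = 1L, source = NA_character_, peak_support = NA_character_)
    noise_pets <- canonicalize_pairs(noise_pets)
  }
  pets <- rbind(planted_pets, noise_pets)
  setorder(pets, chromA, startA, chromB, startB)

  ## ---- peaks --------------------------------------------------------------
  loop_genes <- setdiff(unique(c(loops$geneA, loops$geneB)), NA_character_)
  ## every loop gene carries an H3K4me3 peak (anchors need peak support);
  ## non-loop genes are sampled up to the configured fraction
  n_k4 <- round(cfg$h3k4me3_gene_fraction * nrow(genes))
  extra_pool <- setdiff(genes$gene_id, loop_genes)
  n_extra_k4 <- min(length(extra_pool), max(0, n_k4 - length(loop_genes)))
  k4_genes <- c(loop_genes, if (n_extra_k4 > 0) sample(extra_pool, n_extra_k4))
  rnapii_genes <- sample(genes$gene_id, round(cfg$rnapii_gene_fraction * nrow(genes)))
  peak_at_tss <- function(gene_ids, mark, anchor_boost) {
    g <- genes[gene_id %in% gene_ids]
    w <- as.integer(round(runif(nrow(g), 600, 1500)))
    s <- pmax(0L, g$tss - w %/% 2)
    boost <- ifelse(g$gene_id %in% loop_genes, anchor_boost, 0)
    data.table(peak_id = sprintf("%s_%s", tolower(mark), g$gene_id),
               chrom = g$chrom, start = s, end = s + w,
               intensity = round(exp(rnorm(nrow(g), 1.5 + boost, 0.6)), 3),
               mark = mark)
  }
  k4_peaks <- peak_at_tss(k4_genes, "H3K4me3", anchor_boost = 1)
  if (length(decoy_k4)) {
    dk <- rbindlist(decoy_k4)
    k4_peaks <- rbind(k4_peaks, data.table(
      peak_id = sprintf("h3k4me3_decoy_%d", seq_len(nrow(dk))),
      chrom = dk$chrom, start = dk$start, end = dk$end,
      intensity = round(exp(rnorm(nrow(dk), 1.5, 0.6)), 3), mark = "H3K4me3"))
  }
  rnapii_peaks <- peak_at_tss(rnapii_genes, "RNAPII", anchor_boost = 1)

  ## MNase heavy: planted elements + three decoy classes that the distal
  ## element filters must remove
  heavy <- elements[, .(peak_id = paste0("heavy_", element_id), chrom, start, end,
                        intensity = round(exp(rnorm(.N, 1.2, 0.5)), 3),
                        mark = "MNase_heavy")]
  light_rows <- list()
  nd <- cfg$n_decoy_heavy_per_class
  if (nd > 0) {
    for (i in seq_len(nd)) {  # class 1: heavy overlapped by light
      chrom <- sample(chroms, 1)
      w <- as.integer(round(runif(1, 500, 800)))
      pos <- sample_clear_interval(chrom, w, chrom_lengths[[chrom]], occupied, 500L)
      if (is.null(pos)) next
      add_occupied(chrom, pos[1] - 500L, pos[2] + 500L)
      heavy <- rbind(heavy, data.table(peak_id = sprintf("heavy_decoy_light_%d", i),
                                       chrom = chrom, start = pos[1], end = pos[2],
                                       intensity = 1, mark = "MNase_heavy"))
      light_rows[[length(light_rows) + 1L]] <- data.table(
        peak_id = sprintf("light_%d", i), chrom = chrom,
        start = pos[1] + w %/% 3, end = pos[2] + w %/% 3,
        intensity = 1, mark = "MNase_light")
    }
    for (i in seq_len(nd)) {  # class 2: heavy within 2 kb of a gene
      g <- genes[sample(.N, 1)]
      w <- as.integer(round(runif(1, 500, 800)))
      s <- g$end + as.integer(round(runif(1, 200, 1200)))
      heavy <- rbind(heavy, data.table(peak_id = sprintf("heavy_decoy_gene_%d", i),
                                       chrom = g$chrom, start = s, end = s + w,
                                       intensity = 1, mark = "MNase_heavy"))
    }
    for (i in seq_len(nd)) {  # class 3: heavy in methylated space (no LUMR)
      chrom <- sample(chroms, 1)
      w <- as.integer(round(runif(1, 500, 800)))
      pos <- sample_clear_interval(chrom, w, chrom_lengths[[chrom]], occupied, 500L)
      if (is.null(pos)) next
      add_occupied(chrom, pos[1] - 500L, pos[2] + 500L)
      heavy <- rbind(heavy, data.table(peak_id = sprintf("heavy_decoy_meth_%d", i),
                                       chrom = chrom, start = pos[1], end = pos[2],
                                       intensity = 1, mark = "MNase_heavy"))
    }
  }
  light <- if (length(light_rows)) rbindlist(light_rows) else
    data.table(peak_id = character(), chrom = character(), start = integer(),
               end = integer(), intensity = numeric(), mark = character())
  setorder(heavy, chrom, start); setorder(light, chrom, start)

  ## ---- methylation --------------------------------------------------------
  ctx_cycle <- c("CG", "CHG", "CHH")
  meth <- rbindlist(lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    npos <- floor(len / cfg$meth_site_spacing)
    pos <- as.integer(seq_len(npos) * cfg$meth_site_spacing -
                        sample(cfg$meth_site_spacing, npos, replace = TRUE))
    data.table(chrom = ch, pos = pos,
               context = ctx_cycle[(seq_len(npos) - 1L) %% 3L + 1L])
  }))
  meth[, n_total := pmax(1L, rpois(.N, cfg$meth_coverage_mean))]
  meth[, level := cfg$background_methylation[context]]
  lum_hits <- interval_hits(meth[, .(chrom, start = pos, end = pos + 1L)], lumrs)
  meth[lum_hits$q_idx, level := cfg$lumr_methylation[context]]
  meth[, n_meth := rbinom(.N, n_total, level)]
  meth[, level := NULL]
  setorder(meth, chrom, pos)

  ## ---- expression ---------------------------------------------------------
  coexpr_pairs <- rbindlist(c(
    lapply(ppi_pairs, function(p) data.table(gene1 = p[1], gene2 = p[2])),
    lapply(coexpr_extra, function(p) data.table(gene1 = p[1], gene2 = p[2]))
  ), use.names = TRUE)
  if (is.null(coexpr_pairs) || !nrow(coexpr_pairs)) {
    coexpr_pairs <- data.table(gene1 = character(), gene2 = character())
  }
  coexpr_pairs[, rho := cfg$coexpression_rho]
  nt <- cfg$n_tissues
  mu <- rnorm(nrow(genes), log(10), 1)
  global_factor <- rnorm(nt)
  X <- matrix(rnorm(nrow(genes) * nt), nrow(genes), nt)
  if (cfg$background_rho > 0) {
    X <- sqrt(cfg$background_rho) * matrix(global_factor, nrow(genes), nt, byrow = TRUE) +
      sqrt(1 - cfg$background_rho) * X
  }
  rho <- cfg$coexpression_rho
  if (rho > 0 && nrow(coexpr_pairs)) {
    for (i in seq_len(nrow(coexpr_pairs))) {
      z <- rnorm(nt)
      i1 <- match(coexpr_pairs$gene1[i], genes$gene_id)
      i2 <- match(coexpr_pairs$gene2[i], genes$gene_id)
      X[i1, ] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(nt)
      X[i2, ] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(nt)
    }
  }
  expression <- exp(mu + cfg$expression_sigma * X)
  rownames(expression) <- genes$gene_id
  colnames(expression) <- sprintf("tissue_%02d", seq_len(nt))
  expression <- round(expression, 4)

  ## ---- eQTLs --------------------------------------------------------------
  pdi_loops_dt <- loops[label == "PDI" & eqtl_eligible == TRUE]
  n_linked <- round(cfg$n_eqtls * cfg$eqtl_loop_link_fraction)
  if (n_linked > 0 && !nrow(pdi_loops_dt)) {
    stop("generate_bundle: linked eQTLs require planted PDI loops")
  }
  eqtl_rows <- list()
  if (n_linked > 0) for (i in seq_len(n_linked)) {
    lp <- pdi_loops_dt[sample(.N, 1)]
    el <- elements[element_id == lp$element_id]
    snp <- as.integer(round(runif(1, el$start + 1, el$end - 1)))
    eqtl_rows[[length(eqtl_rows) + 1L]] <- data.table(
      snp_chrom = el$chrom, snp_pos = snp, gene_id = lp$geneB,
      type = "cis", linked = TRUE, loop_id = lp$loop_id)
  }
  n_unlinked <- cfg$n_eqtls - n_linked
  free_genes <- genes[!gene_id %in% loop_genes]
  if (n_unlinked > 0) for (i in seq_len(n_unlinked)) {
    host <- free_genes[sample(.N, 1)]
    snp <- as.integer(round(runif(1, host$start, host$end - 1)))
    assoc <- free_genes[chrom == host$chrom & gene_id != host$gene_id][sample(.N, 1)]
    eqtl_rows[[length(eqtl_rows) + 1L]] <- data.table(
      snp_chrom = host$chrom, snp_pos = snp, gene_id = assoc$gene_id,
      type = "cis", linked = FALSE, loop_id = NA_character_)
  }
  eqtls <- if (length(eqtl_rows)) rbindlist(eqtl_rows) else
    data.table(snp_chrom = character(), snp_pos = integer(), gene_id = character(),
               type = character(), linked = logical(), loop_id = character())

  ## ---- GWAS SNPs ----------------------------------------------------------
  inter_el <- elements[interacting == TRUE]
  n_glink <- round(cfg$n_gwas_snps * cfg$gwas_element_link_fraction)
  if (n_glink > 0 && !nrow(inter_el)) n_glink <- 0L
  gwas_rows <- list()
  ## distinct GWAS loci fall near distinct elements (recycle only when there
  ## are more linked SNPs than interacting elements)
  link_el <- if (n_glink > 0) {
    rep(sample(nrow(inter_el)), length.out = n_glink)
  } else integer(0)
  if (n_glink > 0) for (i in seq_len(n_glink)) {
    el <- inter_el[link_el[i]]
    off <- as.integer(round(runif(1, -cfg$gwas_window / 8, cfg$gwas_window / 8)))
    pos <- min(max(0L, interval_mid(el$start, el$end) + off),
               as.integer(chrom_lengths[[el$chrom]] - 1L))
    gwas_rows[[length(gwas_rows) + 1L]] <- data.table(
      snp_chrom = el$chrom, snp_pos = pos, linked = TRUE)
  }
  n_gun <- cfg$n_gwas_snps - n_glink
  if (n_gun > 0) {
    ch <- sample(chroms, n_gun, replace = TRUE)
    gwas_rows[[length(gwas_rows) + 1L]] <- data.table(
      snp_chrom = ch,
      snp_pos = as.integer(floor(runif(n_gun, 0, chrom_lengths[ch]))),
      linked = FALSE)
  }
  gwas <- if (length(gwas_rows)) rbindlist(gwas_rows) else
    data.table(snp_chrom = character(), snp_pos = integer(), linked = logical())

  list(
    config = cfg,
    chrom_lengths = chrom_lengths,
    genes = genes,
    promoters = promoters,
    peaks = list(H3K4me3 = k4_peaks, RNAPII = rnapii_peaks,
                 MNase_heavy = heavy, MNase_light = light),
    methylation = meth,
    pets = pets,
    expression = expression,
    eqtls = eqtls[, .(snp_chrom, snp_pos, gene_id, type)],
    gwas_snps = gwas[, .(snp_chrom, snp_pos)],
    manifest = list(
      loops = loops,
      lumrs = lumrs,
      distal_elements = elements,
      coexpr_pairs = coexpr_pairs,
      eqtls = eqtls,
      gwas_snps = gwas
    )
  )
}

#' Write a synthetic bundle to disk
#'
#' Emits the standard formats the readers consume: GFF3 genes, BED peaks per
#' mark, methylation/expression/association TSVs, PETs as BEDPE, plus the
#' ground-truth manifest and the configuration as JSON.
#'
#' @param bundle list from [generate_bundle()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_gff3(bundle$genes, fp("genes.gff3"))
  write_bed(bundle$peaks$H3K4me3, fp("peaks_h3k4me3.bed"))
  write_bed(bundle$peaks$RNAPII, fp("peaks_rnapii.bed"))
  write_bed(bundle$peaks$MNase_heavy, fp("peaks_mnase_heavy.bed"))
  write_bed(bundle$peaks$MNase_light, fp("peaks_mnase_light.bed"))
  write_methylation_table(bundle$methylation, fp("methylation.tsv"))
  write_bedpe(bundle$pets, fp("pets.bedpe"))
  write_expression_matrix(bundle$expression, fp("expression.tsv"))
  write_association_table(bundle$eqtls, fp("eqtls.tsv"))
  write_association_table(bundle$gwas_snps, fp("gwas_snps.tsv"))
  jsonlite::write_json(
    list(chrom_lengths = as.list(bundle$chrom_lengths),
         manifest = lapply(bundle$manifest, function(x) as.data.frame(x))),
    fp("manifest.json"), auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(unclass(bundle$config), fp("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic bundle from disk
#'
#' @param dir directory written by [write_bundle()].
#' @return list in the layout of [generate_bundle()].
#' @export
read_bundle <- function(dir) {
  fp <- function(x) file.path(dir, x)
  meta <- jsonlite::read_json(fp("manifest.json"), simplifyVector = TRUE)
  genes <- read_gff3(fp("genes.gff3"))
  chrom_lengths <- unlist(meta$chrom_lengths)
  cfg <- jsonlite::read_json(fp("config.json"), simplifyVector = TRUE)
  list(
    config = cfg,
    chrom_lengths = chrom_lengths,
    genes = genes,
    promoters = call_promoter_regions(genes, cfg$promoter_upstream,
                                      cfg$promoter_downstream, chrom_lengths),
    peaks = list(
      H3K4me3 = read_bed(fp("peaks_h3k4me3.bed"), "H3K4me3"),
      RNAPII = read_bed(fp("peaks_rnapii.bed"), "RNAPII"),
      MNase_heavy = read_bed(fp("peaks_mnase_heavy.bed"), "MNase_heavy"),
      MNase_light = read_bed(fp("peaks_mnase_light.bed"), "MNase_light")
    ),
    methylation = read_methylation_table(fp("methylation.tsv")),
    pets = read_bedpe(fp("pets.bedpe")),
    expression = read_expression_matrix(fp("expression.tsv")),
    eqtls = read_association_table(fp("eqtls.tsv")),
    gwas_snps = read_association_table(fp("gwas_snps.tsv"), require_gene = FALSE),
    manifest = lapply(meta$manifest, as.data.table)
  )
}
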