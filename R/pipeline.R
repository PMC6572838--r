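## End-to-end driver chaining all stages on a (real or synthetic) input
## bundle, plus precision/recall evaluation against a planted ground-truth
## manifest.

#' Default pipeline parameters
#'
#' All stage parameters with their standard values: promoter window 2000/
#' 1500, LUMR thresholds CG < 0.2 / CHG < 0.1 / CHH < 0.1 in 200-bp bins,
#' minimum PET count 3, self-ligation span 8 kb, anchor extension 500 bp,
#' subnetwork edges require PET count > 4, expressed means FPKM > 1,
#' co-expression nulls use 20 log-distance bins, SNP window 4 kb, GWAS
#' window 200 kb.
#'
#' @param ... overrides.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  par <- list(
    promoter_upstream = 2000L,
    promoter_downstream = 1500L,
    lumr_bin_size = 200L,
    lumr_thresholds = c(CG = 0.2, CHG = 0.1, CHH = 0.1),
    lumr_min_coverage = 3L,
    gene_flank = 2000L,
    self_span_threshold = 8000L,
    min_pet_count = 3L,
    anchor_extension = 500L,
    subnetwork_min_pet = 4L,
    expressed_threshold = 1,
    coexpr_bins = 20L,
    coexpr_reps = 100L,
    snp_window = 4000L,
    gwas_window = 200000L,
    enrichment_reps = 200L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(par))
  if (length(unknown)) stop(sprintf("pipeline_params: unknown parameter(s): %s",
                                    paste(unknown, collapse = ", ")))
  par[names(over)] <- over
  if (par$min_pet_count < 1) stop("pipeline_params: min_pet_count must be >= 1")
  if (par$self_span_threshold < 0) stop("pipeline_params: self_span_threshold must be >= 0")
  if (par$coexpr_bins < 1) stop("pipeline_params: coexpr_bins must be >= 1")
  par
}

#' Run the full downstream pipeline on an input bundle
#'
#' Stages in dependency order: promoter/LUMR/distal-element annotation,
#' PET categorization, loop calling, PPI/PDI classification, gene and
#' element categories, looped-pair co-expression against the
#' distance-matched null, and eQTL/GWAS loop integration. Randomized stages
#' draw their seeds deterministically from `params$seed`, so reruns with the
#' same configuration reproduce identical outputs.
#'
#' @param bundle list in [generate_bundle()] layout (or from
#'   [read_bundle()]).
#' @param params list from [pipeline_params()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV/BEDPE plus a provenance JSON (parameters, input digests, seed).
#' @return list with per-stage results.
#' @export
run_pipeline <- function(bundle, params = pipeline_params(), out_dir = NULL) {
  p <- params
  ## per-stage substreams: changing one stage's draws must not perturb others
  stage_seed <- function(k) (p$seed * 97L + k * 1009L) %% .Machine$integer.max

  promoters <- call_promoter_regions(bundle$genes, p$promoter_upstream,
                                     p$promoter_downstream, bundle$chrom_lengths)
  lumrs <- call_lumrs(bundle$methylation, p$lumr_bin_size, p$lumr_thresholds,
                      p$lumr_min_coverage)
  elements <- call_distal_elements(
    bundle$peaks$MNase_heavy, bundle$peaks$MNase_light, bundle$genes,
    bundle$peaks$H3K4me3, lumrs, gene_flank = p$gene_flank)

  pets <- categorize_pets(bundle$pets, p$self_span_threshold)
  loops <- call_loops(pets[category == "inter_ligation"], bundle$peaks$H3K4me3,
                      p$min_pet_count, p$anchor_extension, source = "H3K4me3")
  loop_classes <- classify_loops(loops, promoters, elements)
  gene_cats <- classify_genes(bundle$genes, promoters, loops,
                              rbind(bundle$peaks$H3K4me3, bundle$peaks$RNAPII))
  element_classes <- classify_distal_elements(loop_classes)

  pairs <- ppi_gene_pairs(loop_classes, bundle$genes)
  coexpr <- NULL
  if (nrow(pairs) >= 2) {
    peak_genes <- genes_with_peaks(
      bundle$genes, promoters,
      rbind(bundle$peaks$H3K4me3, bundle$peaks$RNAPII))
    nulls <- matched_random_pairs(pairs, bundle$genes, peak_genes,
                                  n_bins = p$coexpr_bins, reps = p$coexpr_reps,
                                  mode = "B", seed = stage_seed(1L))
    coexpr <- coexpression_test(pairs, nulls, bundle$expression)
  }

  eqtl_res <- NULL; eqtl_enrich <- NULL; eqtl_cats <- NULL
  if (nrow(bundle$eqtls)) {
    eqtl_res <- eqtl_loop_overlap(bundle$eqtls, loops, promoters, p$snp_window)
    eqtl_cats <- classify_eqtl_genes(eqtl_res, loops, promoters, bundle$genes,
                                     p$snp_window, seed = stage_seed(2L))
    if (nrow(loops[chromA == chromB])) {
      eqtl_enrich <- simulate_loops_null(loops, bundle$chrom_lengths,
                                         bundle$eqtls, promoters, p$snp_window,
                                         reps = p$enrichment_reps,
                                         seed = stage_seed(3L))
    }
  }

  gwas_enrich <- NULL
  if (nrow(bundle$gwas_snps) && nrow(elements)) {
    interacting <- elements$element_id %in% element_classes$element_id
    if (any(interacting)) {
      gwas_enrich <- gwas_element_enrichment(
        elements, interacting, bundle$gwas_snps, bundle$chrom_lengths,
        window = p$gwas_window, reps = p$enrichment_reps, seed = stage_seed(4L))
    }
  }

  res <- list(
    params = p,
    promoters = promoters,
    lumrs = lumrs,
    distal_elements = elements,
    pets = pets,
    loops = loops,
    loop_classes = loop_classes,
    gene_categories = gene_cats,
    element_classes = element_classes,
    ppi_pairs = pairs,
    coexpression = coexpr,
    eqtl_overlap = eqtl_res,
    eqtl_gene_categories = eqtl_cats,
    eqtl_enrichment = eqtl_enrich,
    gwas_enrichment = gwas_enrich
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, bundle, out_dir)
  res
}

## serialize stage outputs with a provenance block
write_pipeline_outputs <- function(res, bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  fwrite(res$promoters, fp("promoters.tsv"), sep = "\t")
  fwrite(res$lumrs, fp("lumrs.tsv"), sep = "\t")
  fwrite(res$distal_elements, fp("distal_elements.tsv"), sep = "\t")
  write_bedpe(res$loops, fp("loops.bedpe"))
  fwrite(res$loop_classes, fp("loop_classes.tsv"), sep = "\t")
  fwrite(res$gene_categories, fp("gene_categories.tsv"), sep = "\t")
  fwrite(res$element_classes, fp("element_classes.tsv"), sep = "\t")
  fwrite(res$ppi_pairs, fp("ppi_pairs.tsv"), sep = "\t")
  if (!is.null(res$coexpression)) {
    jsonlite::write_json(res$coexpression[c("mean_difference", "t_test_p", "empirical_p")],
                         fp("coexpression.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$eqtl_overlap)) fwrite(res$eqtl_overlap, fp("eqtl_overlap.tsv"), sep = "\t")
  prov <- list(
    parameters = res$params,
    seed = res$params$seed,
    n_genes = nrow(bundle$genes),
    n_pets = nrow(bundle$pets),
    timestamp_free = TRUE
  )
  jsonlite::write_json(prov, fp("provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

## ---- recovery evaluation --------------------------------------------------

## precision/recall of called vs planted intervals (>= 1 bp overlap match)
interval_recovery <- function(called, planted) {
  if (!nrow(called) || !nrow(planted)) {
    return(list(precision = NA_real_, recall = NA_real_,
                n_called = nrow(called), n_planted = nrow(planted)))
  }
  hits <- interval_hits(called, planted)
  list(precision = length(unique(hits$q_idx)) / nrow(called),
       recall = length(unique(hits$s_idx)) / nrow(planted),
       n_called = nrow(called), n_planted = nrow(planted))
}

## match called loops to planted loops: anchor A overlaps anchor A and
## anchor B overlaps anchor B (both canonical). Returns data.table
## (called_idx, planted_idx).
match_loops <- function(called, planted) {
  called <- as.data.table(called); planted <- as.data.table(planted)
  if (!nrow(called) || !nrow(planted)) {
    return(data.table(called_idx = integer(), planted_idx = integer()))
  }
  hA <- interval_hits(called[, .(chrom = chromA, start = startA, end = endA)],
                      planted[, .(chrom = chromA, start = startA, end = endA)])
  hB <- interval_hits(called[, .(chrom = chromB, start = startB, end = endB)],
                      planted[, .(chrom = chromB, start = startB, end = endB)])
  m <- merge(hA[, .(q_idx, s_idx)], hB[, .(q_idx, s_idx)], by = c("q_idx", "s_idx"))
  unique(data.table(called_idx = m$q_idx, planted_idx = m$s_idx))
}

#' Evaluate pipeline results against a planted ground-truth manifest
#'
#' Computes precision and recall for called loops, LUMRs and distal
#' elements, the accuracy of PPI/PDI labels on recovered loops, and
#' precision/recall of looped eQTL-etrait pair detection.
#'
#' @param res list from [run_pipeline()].
#' @param manifest `manifest` element of a [generate_bundle()] bundle.
#' @return data.table with `metric`, `value`.
#' @export
evaluate_against_manifest <- function(res, manifest) {
  planted_loops <- as.data.table(manifest$loops)
  lm <- match_loops(res$loops, planted_loops)
  loop_prec <- if (nrow(res$loops)) length(unique(lm$called_idx)) / nrow(res$loops) else NA_real_
  loop_rec <- if (nrow(planted_loops)) length(unique(lm$planted_idx)) / nrow(planted_loops) else NA_real_

  lum <- interval_recovery(res$lumrs, as.data.table(manifest$lumrs))
  de <- interval_recovery(res$distal_elements, as.data.table(manifest$distal_elements))

  ## label accuracy over 1:1 matched loops
  lab_acc <- NA_real_
  if (nrow(lm)) {
    lm1 <- lm[!duplicated(called_idx)][!duplicated(planted_idx)]
    called_lab <- res$loop_classes$label[lm1$called_idx]
    planted_lab <- planted_loops$label[lm1$planted_idx]
    lab_acc <- mean(called_lab == planted_lab)
  }

  ## eQTL link recovery
  eq_prec <- NA_real_; eq_rec <- NA_real_
  if (!is.null(res$eqtl_overlap) && "linked" %in% names(manifest$eqtls)) {
    truth <- as.data.table(manifest$eqtls)$linked
    found <- res$eqtl_overlap$looped
    if (sum(found)) eq_prec <- sum(found & truth) / sum(found)
    if (sum(truth)) eq_rec <- sum(found & truth) / sum(truth)
  }

  data.table(
    metric = c("loop_precision", "loop_recall", "lumr_precision", "lumr_recall",
               "distal_element_precision", "distal_element_recall",
               "loop_label_accuracy", "eqtl_link_precision", "eqtl_link_recall"),
    value = c(loop_prec, loop_rec, lum$precision, lum$recall,
              de$precision, de$recall, lab_acc, eq_prec, eq_rec)
  )
}
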