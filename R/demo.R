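# End-to-end orchestration of the simulated study: simulate -> consensus
# peaks -> differential (ATAC, RNA, eRNA) -> annotation -> conservation ->
# eRNA -> eQTL linking -> context enrichment, with all tables written under
# an output directory.

#' Match consensus peaks to the true planted peaks
#'
#' Each consensus peak is matched to the true peak it overlaps most. Used
#' to transfer simulated count rows onto the consensus set and to join
#' pipeline results with the truth table.
#'
#' @param consensus consensus `GRanges` with `id`.
#' @param truth ATAC truth table.
#' @return data.frame: `peak_id` (consensus), `true_peak_id`.
#' @export
match_consensus_to_truth <- function(consensus, truth) {
  tg <- genomic_intervals(truth$chrom, truth$start, truth$end,
                          id = truth$peak_id)
  hits <- findOverlaps(consensus, tg)
  ov <- width(IRanges::pintersect(
    IRanges::ranges(consensus)[queryHits(hits)],
    IRanges::ranges(tg)[subjectHits(hits)]
  ))
  h <- data.frame(q = queryHits(hits), s = subjectHits(hits), ov = ov)
  h <- h[order(h$q, -h$ov, h$s), ]
  h <- h[!duplicated(h$q), ]
  data.frame(
    peak_id = mcols(consensus)$id[h$q],
    true_peak_id = truth$peak_id[h$s],
    stringsAsFactors = FALSE
  )
}

# Re-key a simulated count matrix (rows = true feature ids) onto pipeline
# feature ids via an id map (pipeline id -> true id).
transfer_counts <- function(cm, map_from, map_to) {
  m <- assay(cm, "counts")
  keep <- map_to %in% rownames(m)
  m2 <- m[map_to[keep], , drop = FALSE]
  rownames(m2) <- map_from[keep]
  count_matrix(m2, as.data.frame(colData(cm)))
}

#' Run the full pipeline on simulated data
#'
#' Simulates a study, builds the recurrent peak set from the per-sample
#' calls, tests differential accessibility/expression for every
#' stimulated-vs-UT contrast, annotates peaks (distal/proximal, distal
#' enrichment, conservation profiles by differential status), defines and
#' quantifies eRNA regions with the fold-change correlation, links peaks to
#' eGenes through the simulated eQTL catalogue, and runs the
#' context-specificity enrichment. Writes every table as TSV/BED under
#' `outdir` (when given) plus a one-row summary.
#'
#' @param spec a [simulation_spec()].
#' @param outdir output directory (NULL for in-memory only).
#' @param focal_condition condition for the context-specificity test
#'   ("IFNG").
#' @param reference_conditions comparison condition(s) ("LPS24").
#' @param config a [pipeline_config()].
#' @return list with every intermediate result and a `summary` data.frame.
#' @export
run_demo <- function(spec = simulation_spec(), outdir = NULL,
                     focal_condition = "IFNG", reference_conditions = "LPS24",
                     config = pipeline_config()) {
  sim <- simulate_study(spec)
  contrasts <- setdiff(CONDITIONS, "UT")

  # consensus peaks from filtered per-sample calls
  filtered <- filter_sample_peaks(sim$atac$calls, sim$atac$blacklist,
                                  config$peak_p_threshold)
  consensus <- build_recurrent(filtered, n_samples = nrow(sim$atac$samples),
                               recurrence_fraction = config$recurrence_fraction)
  tmap <- match_consensus_to_truth(consensus, sim$atac$truth)
  atac_counts <- transfer_counts(sim$atac$counts, tmap$peak_id, tmap$true_peak_id)

  # differential testing, all stimulated-vs-UT contrasts
  atac_sf <- size_factors(atac_counts)
  atac_res <- lapply(contrasts, function(cc) {
    call_differential(nb_wald(atac_counts, cc, "UT", sf = atac_sf),
                      config$atac_fc, config$fdr)
  })
  names(atac_res) <- contrasts

  gene_cm <- filter_expressed_genes(sim$rna$gene_counts, config$gene_min_count,
                                    config$gene_min_fraction)
  rna_sf <- size_factors(gene_cm)
  rna_res <- lapply(contrasts, function(cc) {
    call_differential(nb_wald(gene_cm, cc, "UT", sf = rna_sf),
                      config$gene_fc, config$fdr)
  })
  names(rna_res) <- contrasts

  # annotation and conservation
  annot <- classify_tss_distance(consensus, sim$annotation$genes,
                                 config$tss_window_bp)
  diff_any <- Reduce(`|`, lapply(atac_res, function(r) {
    r$is_differential[match(annot$peak_id, r$feature_id)]
  }))
  diff_any[is.na(diff_any)] <- FALSE
  enrich <- distal_enrichment(diff_any, annot$is_distal)
  prof_diff <- conservation_profile(consensus[diff_any], sim$conservation,
                                    config$conservation_halfwidth_bp,
                                    config$conservation_bin_bp)
  prof_nondiff <- conservation_profile(consensus[!diff_any], sim$conservation,
                                       config$conservation_halfwidth_bp,
                                       config$conservation_bin_bp)

  # eRNA regions, counts, expression filter, fold-change correlation
  expr_ids <- expressed_genes(sim$rna$gene_counts, config$expressed_tpm_min)
  regions <- define_erna_regions(consensus, sim$annotation$genes, expr_ids,
                                 config$gene_boundary_pad_bp,
                                 config$erna_halfwidth_bp)
  region_map <- data.frame(
    region_id = mcols(regions)$id,
    source_peak_id = mcols(regions)$source_peak_id,
    stringsAsFactors = FALSE
  )
  true_region_id <- paste0(tmap$true_peak_id[match(region_map$source_peak_id,
                                                   tmap$peak_id)], "_eRNA")
  erna_counts <- transfer_counts(sim$rna$erna_counts, region_map$region_id,
                                 true_region_id)
  lib <- colSums(assay(sim$rna$gene_counts, "counts")) +
    colSums(assay(sim$rna$erna_counts, "counts"))
  eflags <- erna_cpm_flags(assay(erna_counts, "counts"), lib, config$erna_cpm_min)
  erna_expr <- erna_counts[eflags$is_expressed, ]
  erna_res <- lapply(contrasts, function(cc) {
    call_differential(nb_wald(erna_expr, cc, "UT"), config$erna_fc, config$fdr)
  })
  names(erna_res) <- contrasts
  corr_pairs <- do.call(rbind, lapply(contrasts, function(cc) {
    res <- tryCatch(
      erna_atac_correlation(erna_res[[cc]], atac_res[[cc]], region_map),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    cbind(contrast = cc, res$pairs)
  }))
  erna_corr <- if (!is.null(corr_pairs) && nrow(corr_pairs) >= 3) {
    pearson_r(corr_pairs$erna_log2fc, corr_pairs$atac_log2fc)
  } else list(r = NA_real_, p = NA_real_, n = 0L)

  # eQTL linking and context-specificity enrichment
  links <- assign_egenes(consensus, sim$eqtl, config$eqtl_p_threshold)
  concord <- tryCatch(
    atac_egene_concordance(links, atac_res[[focal_condition]],
                           rna_res[[focal_condition]]),
    error = function(e) list(r = NA_real_, p = NA_real_, n = 0L)
  )
  diff_peak_ids <- atac_res[[focal_condition]]$feature_id[
    atac_res[[focal_condition]]$is_differential]
  de_gene_ids <- rna_res[[focal_condition]]$feature_id[
    rna_res[[focal_condition]]$is_differential]
  context <- context_specific_enrichment(links, sim$eqtl, diff_peak_ids,
                                         de_gene_ids, focal_condition,
                                         reference_conditions)

  summary <- data.frame(
    seed = spec$seed,
    n_consensus_peaks = length(consensus),
    n_differential_peaks_any = sum(diff_any),
    frac_distal = mean(annot$is_distal),
    distal_enrichment_p = enrich$p,
    distal_enrichment_or = enrich$or,
    n_erna_regions = length(regions),
    frac_erna_expressed = mean(eflags$is_expressed),
    erna_atac_r = erna_corr$r,
    erna_atac_n = erna_corr$n,
    n_links = nrow(links),
    concordance_r = concord$r,
    concordance_n = concord$n,
    context_or = context$or,
    context_p = context$p
  )

  out <- list(sim = sim, consensus = consensus, truth_map = tmap,
              atac_counts = atac_counts, atac_results = atac_res,
              rna_results = rna_res, annotation = annot, enrichment = enrich,
              profile_differential = prof_diff,
              profile_nondifferential = prof_nondiff,
              erna_regions = regions, region_map = region_map,
              erna_counts = erna_counts, erna_expressed = eflags$is_expressed,
              erna_results = erna_res, erna_correlation = erna_corr,
              erna_pairs = corr_pairs,
              links = links, concordance = concord, context = context,
              summary = summary)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_bed(consensus, file.path(outdir, "consensus_peaks.bed"))
    write_counts_tsv(atac_counts, file.path(outdir, "atac_counts.tsv"),
                     feature_col = "peak_id")
    for (cc in contrasts) {
      fwrite(atac_res[[cc]], file.path(outdir, paste0("differential_atac_", cc, "_vs_UT.tsv")), sep = "\t")
      fwrite(rna_res[[cc]], file.path(outdir, paste0("differential_rna_", cc, "_vs_UT.tsv")), sep = "\t")
      fwrite(erna_res[[cc]], file.path(outdir, paste0("differential_erna_", cc, "_vs_UT.tsv")), sep = "\t")
    }
    fwrite(annot, file.path(outdir, "peak_annotation.tsv"), sep = "\t")
    fwrite(prof_diff, file.path(outdir, "conservation_profile_differential.tsv"), sep = "\t")
    fwrite(prof_nondiff, file.path(outdir, "conservation_profile_nondifferential.tsv"), sep = "\t")
    write_bed(regions, file.path(outdir, "erna_regions.bed"))
    fwrite(links, file.path(outdir, "egene_links.tsv"), sep = "\t")
    ctab <- context$table
    fwrite(data.frame(cell = c("focal_in_set", "focal_out", "reference_in_set",
                               "reference_out"),
                      count = as.integer(t(ctab))),
           file.path(outdir, "context_enrichment_table.tsv"), sep = "\t")
    fwrite(summary, file.path(outdir, "summary.tsv"), sep = "\t")
  }
  out
}
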