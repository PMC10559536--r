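# Parameter-recovery evaluation of a pipeline run against the simulator's
# truth tables: realized FDR and sensitivity of the differential calls, the
# eRNA-ATAC correlation estimate, the context-specificity enrichment, and
# the ordering of the conservation profiles.

#' Score a pipeline run against simulated truth
#'
#' Pools the differential calls of every stimulated-vs-UT contrast (ATAC
#' and RNA) and computes the realized false discovery rate (a feature is a
#' false discovery for a contrast when it carries no planted effect in that
#' contrast's condition) and the sensitivity among features with a strong
#' planted effect (|log2FC| > 1).
#'
#' @param res a [run_demo()] result.
#' @return one-row data.frame: `fdr_realized`, `sensitivity`, `n_called`,
#'   `erna_r`, `erna_n`, `context_or`, `context_p`,
#'   `conservation_gap_center` (mean non-differential minus differential
#'   profile over the central 20 bins), `conservation_ordered` (TRUE when
#'   every central bin keeps that order), `frac_distal`, `distal_or`,
#'   `frac_erna_expressed`.
#' @export
recovery_metrics <- function(res) {
  truth <- res$sim$atac$truth
  tmap <- res$truth_map
  gene_truth <- res$sim$rna$gene_truth
  fp <- called <- tp <- strong <- 0
  for (cc in names(res$atac_results)) {
    r <- res$atac_results[[cc]]
    tt <- truth[match(tmap$true_peak_id[match(r$feature_id, tmap$peak_id)],
                      truth$peak_id), ]
    null <- is.na(tt$diff_condition) | tt$diff_condition != cc
    fp <- fp + sum(r$is_differential & null)
    called <- called + sum(r$is_differential)
    str_i <- !null & abs(tt$true_lfc) > 1
    tp <- tp + sum(r$is_differential & str_i)
    strong <- strong + sum(str_i)

    g <- res$rna_results[[cc]]
    gt <- gene_truth[match(g$feature_id, gene_truth$gene_id), ]
    gnull <- is.na(gt$diff_condition) | gt$diff_condition != cc
    fp <- fp + sum(g$is_differential & gnull)
    called <- called + sum(g$is_differential)
  }
  ctr <- abs(res$profile_differential$bin_center) <= 100
  gap <- res$profile_nondifferential$mean_score[ctr] -
    res$profile_differential$mean_score[ctr]
  data.frame(
    fdr_realized = if (called) fp / called else 0,
    sensitivity = if (strong) tp / strong else NA_real_,
    n_called = called,
    erna_r = res$erna_correlation$r,
    erna_n = res$erna_correlation$n,
    context_or = res$context$or,
    context_p = res$context$p,
    conservation_gap_center = mean(gap),
    conservation_ordered = all(gap > 0),
    frac_distal = res$summary$frac_distal,
    distal_or = res$summary$distal_enrichment_or,
    frac_erna_expressed = res$summary$frac_erna_expressed
  )
}
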