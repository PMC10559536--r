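# eQTL-based enhancer-gene linking: assign each consensus peak at most one
# eGene via its most significant in-peak eQTL, correlate ATAC change with
# eGene expression change, and test whether lead eQTLs of the focal
# stimulation are enriched among focal differential-peak/DE-gene links
# relative to leads of a comparison condition.

#' Assign eGenes to peaks via the most significant in-peak eQTL
#'
#' Considers eQTL records with `p < p_threshold` (strict) whose position
#' falls inside the peak (half-open), and links the peak to the gene of the
#' single most significant record over all variants, genes and conditions.
#' Ties at the minimum p are broken by the smaller best p across the other
#' conditions for the same variant-gene pair, then smaller position, then
#' lexicographic gene id, so the output is independent of input order.
#'
#' @param peaks consensus `GRanges` with `id` metadata.
#' @param eqtl eQTL data.frame ([read_eqtl_tsv()]; 0-based `pos`).
#' @param p_threshold association p cutoff (default 1e-5).
#' @return data.frame: `peak_id`, `gene_id`, `variant_id`, `p`,
#'   `condition`; at most one row per peak.
#' @export
assign_egenes <- function(peaks, eqtl, p_threshold = 1e-05) {
  eq <- eqtl[eqtl$p < p_threshold, , drop = FALSE]
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      variant_id = character(), p = numeric(),
                      condition = character(), stringsAsFactors = FALSE)
  if (!nrow(eq)) return(empty)
  # secondary significance: best p of the same variant-gene pair in its
  # other conditions (used only to break exact ties)
  key <- paste(eq$variant_id, eq$gene_id)
  grp <- split(seq_len(nrow(eqtl)), paste(eqtl$variant_id, eqtl$gene_id))
  second <- vapply(seq_len(nrow(eq)), function(i) {
    j <- grp[[key[i]]]
    ps <- eqtl$p[j][eqtl$condition[j] != eq$condition[i]]
    if (length(ps)) min(ps) else 1
  }, numeric(1))
  vgr <- GRanges(eq$chrom, IRanges(eq$pos + 1L, eq$pos + 1L))
  hits <- findOverlaps(vgr, peaks)
  if (!length(hits)) return(empty)
  cand <- data.frame(
    peak_id = mcols(peaks)$id[subjectHits(hits)],
    gene_id = eq$gene_id[queryHits(hits)],
    variant_id = eq$variant_id[queryHits(hits)],
    p = eq$p[queryHits(hits)],
    condition = eq$condition[queryHits(hits)],
    pos = eq$pos[queryHits(hits)],
    second = second[queryHits(hits)],
    stringsAsFactors = FALSE
  )
  cand <- cand[order(cand$peak_id, cand$p, cand$second, cand$pos, cand$gene_id), ]
  out <- cand[!duplicated(cand$peak_id), c("peak_id", "gene_id", "variant_id",
                                           "p", "condition")]
  rownames(out) <- NULL
  ern_log("eGene links: ", nrow(out), " of ", length(peaks), " peaks linked")
  out
}

#' Correlate ATAC change of differential peaks with eGene expression change
#'
#' Pairs each differential peak's ATAC log2 fold change with its linked
#' eGene's RNA log2 fold change for the same contrast.
#'
#' @param links output of [assign_egenes()].
#' @param atac_results,rna_results [nb_wald()] results for one contrast.
#' @return list: `r`, `p`, `n`, `pairs`.
#' @export
atac_egene_concordance <- function(links, atac_results, rna_results) {
  a <- atac_results[match(links$peak_id, atac_results$feature_id), , drop = FALSE]
  g <- rna_results[match(links$gene_id, rna_results$feature_id), , drop = FALSE]
  ok <- !is.na(a$log2fc) & !is.na(g$log2fc) & a$is_differential
  pairs <- data.frame(
    peak_id = links$peak_id[ok], gene_id = links$gene_id[ok],
    atac_log2fc = a$log2fc[ok], gene_log2fc = g$log2fc[ok],
    stringsAsFactors = FALSE
  )
  if (nrow(pairs) < 3) stop("insufficient pairs (need >= 3, have ", nrow(pairs), ")")
  ct <- pearson_r(pairs$atac_log2fc, pairs$gene_log2fc)
  list(r = ct$r, p = ct$p, n = ct$n, pairs = pairs)
}

#' Context-specificity enrichment of lead eQTLs
#'
#' Restricts lead eQTLs to those residing in linked peaks, defines the
#' "matched set" as links whose peak is differential in the focal contrast
#' AND whose eGene is differentially expressed in the focal contrast, and
#' tests whether leads identified in the focal condition fall in that set
#' more often than leads identified in a comparison condition:
#' rows = lead condition (focal vs reference), columns = in matched set vs
#' not; two-tailed Fisher exact test with conditional-MLE odds ratio.
#'
#' @param links output of [assign_egenes()].
#' @param eqtl eQTL data.frame with `is_lead` and `condition`.
#' @param diff_peak_ids peak ids differential in the focal contrast.
#' @param de_gene_ids gene ids differentially expressed in the focal
#'   contrast.
#' @param focal_condition condition whose leads are tested (e.g. "IFNG").
#' @param reference_conditions comparison condition(s) (e.g. "LPS24").
#' @return list: `table` (2x2), `p`, `or`, `degenerate`,
#'   `prop_focal`, `prop_reference`.
#' @export
context_specific_enrichment <- function(links, eqtl, diff_peak_ids, de_gene_ids,
                                        focal_condition, reference_conditions) {
  leads <- eqtl[eqtl$is_lead &
                  eqtl$condition %in% c(focal_condition, reference_conditions), ,
                drop = FALSE]
  # a lead participates when its variant carries a link
  idx <- match(leads$variant_id, links$variant_id)
  leads <- leads[!is.na(idx), , drop = FALSE]
  lk <- links[idx[!is.na(idx)], , drop = FALSE]
  if (!nrow(leads)) {
    return(list(table = matrix(0L, 2, 2), p = 1, or = NA_real_,
                degenerate = TRUE, prop_focal = NA_real_,
                prop_reference = NA_real_))
  }
  in_set <- lk$peak_id %in% diff_peak_ids & lk$gene_id %in% de_gene_ids
  focal <- leads$condition == focal_condition
  a <- sum(focal & in_set)
  b <- sum(focal & !in_set)
  c_ <- sum(!focal & in_set)
  d <- sum(!focal & !in_set)
  ft <- fisher_exact_two_tailed(a, b, c_, d)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c(focal_condition,
                                  paste(reference_conditions, collapse = "+")),
                                c("matched_set", "other")))
  list(table = tab, p = ft$p_two_tailed, or = ft$or_cmle,
       degenerate = ft$degenerate,
       prop_focal = if (a + b) a / (a + b) else NA_real_,
       prop_reference = if (c_ + d) c_ / (c_ + d) else NA_real_)
}
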