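# Enhancer-RNA analysis: expressed-gene definition (TPM), candidate eRNA
# regions from distal consensus-peak midpoints away from expressed-gene
# boundaries, RNA quantification with a CPM filter, and the eRNA-vs-ATAC
# fold-change correlation.

#' TPM matrix and expressed-gene set
#'
#' TPM for gene g in sample s is `(count / length_kb) /
#' sum_g(count / length_kb) * 1e6`. A gene is expressed when its maximum
#' TPM across samples reaches `tpm_min` (non-strict).
#'
#' @param cm RNA `SummarizedExperiment` with a `length` rowData column.
#' @return `tpm_matrix()`: the numeric TPM matrix (each column sums to
#'   1e6).
#' @export
tpm_matrix <- function(cm) {
  len <- rowData(cm)$length
  if (is.null(len)) stop("feature lengths required for TPM")
  m <- assay(cm, "counts")
  rate <- m / (len / 1e3)
  denom <- colSums(rate)
  if (any(denom == 0)) stop("zero library: no expressed feature in some sample")
  sweep(rate, 2, denom, "/") * 1e6
}

#' @rdname tpm_matrix
#' @param tpm_min max-TPM threshold (default 0.5).
#' @return `expressed_genes()`: character vector of expressed gene ids.
#' @export
expressed_genes <- function(cm, tpm_min = 0.5) {
  tpm <- tpm_matrix(cm)
  ids <- rownames(tpm)[apply(tpm, 1, max) >= tpm_min]
  ern_log("expressed genes (max TPM >= ", tpm_min, "): ", length(ids),
          " of ", nrow(tpm))
  ids
}

#' Define candidate eRNA regions
#'
#' Each consensus peak contributes the window midpoint +/- `halfwidth`;
#' a window is dropped when it overlaps, by at least 1 bp, the padded
#' boundary `[start - pad, end + pad)` of any expressed gene.
#' Non-expressed genes impose no exclusion.
#'
#' @param consensus consensus `GRanges` with `id` metadata.
#' @param genes gene annotation data.frame.
#' @param expressed_ids ids of expressed genes ([expressed_genes()]).
#' @param pad gene-boundary pad in bp (default 3000).
#' @param halfwidth window half-width in bp (default 1000).
#' @return `GRanges` of surviving regions with metadata `id`
#'   (`<peak_id>_eRNA`) and `source_peak_id`.
#' @export
define_erna_regions <- function(consensus, genes, expressed_ids,
                                pad = 3000, halfwidth = 1000) {
  mid <- interval_midpoint0(consensus)
  regions <- genomic_intervals(
    as.character(seqnames(consensus)),
    pmax(mid - halfwidth, 0L), mid + halfwidth,
    id = paste0(mcols(consensus)$id, "_eRNA"),
    source_peak_id = mcols(consensus)$id
  )
  expr <- genes[genes$gene_id %in% expressed_ids, , drop = FALSE]
  if (nrow(expr)) {
    padded <- genomic_intervals(expr$chrom, pmax(expr$start - pad, 0L),
                                expr$end + pad)
    keep <- countOverlaps(regions, padded, minoverlap = 1L) == 0
  } else {
    keep <- rep(TRUE, length(regions))
  }
  ern_log("eRNA regions: ", sum(keep), " of ", length(regions),
          " candidate windows clear of padded expressed-gene boundaries")
  regions[keep]
}

#' Quantify RNA signal in eRNA regions
#'
#' Counts fragments overlapping each region by at least 1 bp (unstranded),
#' then applies the CPM expression filter via [erna_cpm_flags()] using each
#' sample's total fragment count as library size.
#'
#' @param regions eRNA `GRanges` with `id` metadata.
#' @param fragments named list (by sample id) of RNA fragment `GRanges`.
#' @param samples sample sheet covering the fragment samples.
#' @param cpm_min max-CPM threshold (default 1, non-strict).
#' @return list: `counts` (`SummarizedExperiment`), `max_cpm`,
#'   `is_expressed` (named by region id).
#' @export
quantify_erna <- function(regions, fragments, samples, cpm_min = 1) {
  samples <- validate_sample_sheet(samples)
  lib <- vapply(samples$sample_id, function(s) length(fragments[[s]]), numeric(1))
  if (any(lib == 0)) stop("zero library size for sample(s): ",
                          paste(samples$sample_id[lib == 0], collapse = ", "))
  m <- vapply(samples$sample_id, function(s) {
    countOverlaps(regions, fragments[[s]], minoverlap = 1L)
  }, integer(length(regions)))
  m <- matrix(m, nrow = length(regions),
              dimnames = list(mcols(regions)$id, samples$sample_id))
  flags <- erna_cpm_flags(m, lib, cpm_min)
  list(counts = count_matrix(m, samples), max_cpm = flags$max_cpm,
       is_expressed = flags$is_expressed)
}

#' @rdname quantify_erna
#' @param counts region x sample count matrix.
#' @param lib_sizes per-sample library sizes (total fragment counts).
#' @return `erna_cpm_flags()`: list with `max_cpm` and `is_expressed`.
#' @export
erna_cpm_flags <- function(counts, lib_sizes, cpm_min = 1) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  cpm <- sweep(counts, 2, lib_sizes, "/") * 1e6
  max_cpm <- apply(cpm, 1, max)
  list(max_cpm = max_cpm, is_expressed = max_cpm >= cpm_min)
}

#' Correlate eRNA and ATAC fold changes
#'
#' Pairs each eRNA region's log2 fold change with its source peak's ATAC
#' log2 fold change for one contrast, restricted to regions whose eRNA is
#' differential (optionally also requiring the ATAC side), and returns the
#' Pearson correlation.
#'
#' @param erna_results [nb_wald()] results for eRNA regions (feature ids =
#'   region ids).
#' @param atac_results [nb_wald()] results for consensus peaks.
#' @param region_map data.frame with `region_id`, `source_peak_id`.
#' @param require_both also require the ATAC peak to be differential
#'   (default FALSE).
#' @return list: `r`, `p`, `n`, `pairs` (data.frame of the paired fold
#'   changes).
#' @export
erna_atac_correlation <- function(erna_results, atac_results, region_map,
                                  require_both = FALSE) {
  e <- erna_results[erna_results$is_differential, , drop = FALSE]
  idx <- match(e$feature_id, region_map$region_id)
  peak <- region_map$source_peak_id[idx]
  a <- atac_results[match(peak, atac_results$feature_id), , drop = FALSE]
  ok <- !is.na(peak) & !is.na(a$log2fc)
  if (require_both) ok <- ok & a$is_differential
  pairs <- data.frame(
    region_id = e$feature_id[ok],
    peak_id = peak[ok],
    erna_log2fc = e$log2fc[ok],
    atac_log2fc = a$log2fc[ok],
    stringsAsFactors = FALSE
  )
  if (nrow(pairs) < 3) stop("insufficient pairs (need >= 3, have ", nrow(pairs), ")")
  ct <- pearson_r(pairs$erna_log2fc, pairs$atac_log2fc)
  list(r = ct$r, p = ct$p, n = ct$n, pairs = pairs)
}
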