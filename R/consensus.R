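# Recurrent (consensus) ATAC peak construction: per-sample call filtering,
# cross-sample single-linkage merging with a distinct-sample support rule,
# and fragment counting over the consensus set. Overlap everywhere means
# >= 1 bp on half-open intervals.

#' Filter per-sample peak calls
#'
#' Drops a peak when its call p-value exceeds `p_threshold` (i.e. its
#' -log10 p is below the threshold; a peak at exactly the threshold is
#' kept) or when it overlaps a blacklist interval by at least 1 bp.
#'
#' @param peaks `GRanges` with metadata `sample_id` and `neglog10_p`.
#' @param blacklist `GRanges` of excluded regions (may be empty or NULL).
#' @param p_threshold peak-call p-value cutoff (default 1e-5).
#' @return The filtered `GRanges`.
#' @export
filter_sample_peaks <- function(peaks, blacklist = NULL, p_threshold = 1e-05) {
  need <- c("sample_id", "neglog10_p")
  if (!all(need %in% names(mcols(peaks)))) {
    stop("peaks need metadata columns sample_id and neglog10_p")
  }
  keep <- mcols(peaks)$neglog10_p >= -log10(p_threshold)
  if (!is.null(blacklist) && length(blacklist)) {
    keep <- keep & countOverlaps(peaks, blacklist) == 0
  }
  ern_log("peak filter: ", sum(keep), " of ", length(peaks), " calls retained")
  peaks[keep]
}

#' Build the recurrent (consensus) peak set
#'
#' Clusters filtered per-sample peaks by single-linkage >= 1 bp overlap
#' across all samples, counts the distinct samples supporting each cluster,
#' and keeps clusters supported by at least `ceiling(recurrence_fraction *
#' n_samples)` samples. The consensus interval is the union (min start, max
#' end) of the cluster members.
#'
#' @param peaks filtered `GRanges` with `sample_id` metadata.
#' @param n_samples total number of samples in the study (not just those
#'   contributing peaks).
#' @param recurrence_fraction minimum supporting-sample fraction (default
#'   0.30).
#' @return `GRanges` sorted by (chrom, start) with metadata `peak_id`
#'   (`peak_00001`, ... in sorted order), `n_supporting_samples` and a
#'   `member_sample_ids` CharacterList.
#' @export
build_recurrent <- function(peaks, n_samples, recurrence_fraction = 0.30) {
  if (n_samples <= 0) stop("n_samples must be positive")
  merged <- reduce(peaks, min.gapwidth = 0L)
  merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)
  hits <- findOverlaps(peaks, merged, minoverlap = 1L)
  supp <- split(mcols(peaks)$sample_id[queryHits(hits)], subjectHits(hits))
  supp_ids <- lapply(supp, function(s) sort(unique(s)))
  n_supp <- integer(length(merged))
  n_supp[as.integer(names(supp_ids))] <- lengths(supp_ids)
  min_supp <- ceiling(recurrence_fraction * n_samples)
  keep <- n_supp >= min_supp
  out <- merged[keep]
  mcols(out)$n_supporting_samples <- n_supp[keep]
  members <- vector("list", length(merged))
  members[as.integer(names(supp_ids))] <- supp_ids
  mcols(out)$member_sample_ids <- IRanges::CharacterList(members[keep])
  mcols(out)$id <- sprintf("peak_%05d", seq_along(out))
  ern_log("recurrent peaks: ", length(out), " of ", length(merged),
          " clusters with support >= ", min_supp, " of ", n_samples, " samples")
  out
}

#' Count fragments over consensus peaks
#'
#' `count[peak, sample]` is the number of that sample's fragments
#' overlapping the peak by at least 1 bp; a fragment overlapping two peaks
#' contributes to both.
#'
#' @param consensus consensus `GRanges` with `id` metadata.
#' @param fragments named list (by sample id) of fragment `GRanges`.
#' @param samples sample sheet covering the fragment samples.
#' @return A `SummarizedExperiment` of integer counts.
#' @export
count_fragments <- function(consensus, fragments, samples) {
  samples <- validate_sample_sheet(samples)
  if (!all(samples$sample_id %in% names(fragments))) {
    stop("fragments missing for some samples in the sheet")
  }
  m <- vapply(samples$sample_id, function(s) {
    countOverlaps(consensus, fragments[[s]], minoverlap = 1L)
  }, integer(length(consensus)))
  m <- matrix(m, nrow = length(consensus),
              dimnames = list(mcols(consensus)$id, samples$sample_id))
  count_matrix(m, samples)
}
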